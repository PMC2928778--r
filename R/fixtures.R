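fixture_names <- c("mcf10a_counts", "yvma_counts", "doubling_times",
                   "s2_vectors", "s3_vectors", "robustness_ranges")

#' Load a packaged quantitative fixture table
#'
#' Machine-readable transcriptions of the experimental anchors used for
#' calibration and testing: per-day cross-section areas and cell counts for
#' MCF10A and HER2-YVMA 3D cultures, effective doubling times, the five
#' hollow-acinus and five mutant threshold vectors, and the robustness
#' ranges of the tuned baseline. Each row carries a provenance string.
#'
#' @param name one of `r paste0('\x60', fixture_names, '\x60', collapse = ", ")`.
#' @return a data frame.
#' @export
load_fixture <- function(name) {
  if (!name %in% fixture_names)
    stop("unknown fixture: ", name, " (available: ",
         paste(fixture_names, collapse = ", "), ")")
  path <- system.file("extdata", paste0(name, ".csv"), package = "ibcell",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Fixture file checksums
#'
#' md5 of every packaged fixture, so tests can lock the transcribed values.
#'
#' @return named character vector of md5 strings.
#' @export
fixture_checksums <- function() {
  paths <- vapply(fixture_names, function(n)
    system.file("extdata", paste0(n, ".csv"), package = "ibcell",
                mustWork = TRUE), character(1))
  stats::setNames(unname(tools::md5sum(paths)), fixture_names)
}

#' Reshape a count fixture into a tuner target table
#'
#' @param table a fixture table with `day`, `count_mean`, `count_sd`
#'   (e.g. `load_fixture("mcf10a_counts")`), or a cell-line name
#'   (`"mcf10a"`, `"yvma"`).
#' @param days optional subset of checkpoint days.
#' @param path optional CSV file to write (the tuner CLI format).
#' @return data frame with `day`, `total_mean`, `total_sd`, `grow_mean`,
#'   `grow_sd`, `die_mean`, `die_sd` (growth/death columns `NA`: only total
#'   counts are transcribed).
#' @export
emit_targets <- function(table, days = NULL, path = NULL) {
  if (is.character(table))
    table <- load_fixture(paste0(tolower(table), "_counts"))
  if (!is.null(days)) table <- table[table$day %in% days, , drop = FALSE]
  k <- length(table$day)
  out <- data.frame(day = table$day,
                    total_mean = table$count_mean,
                    total_sd = table$count_sd,
                    grow_mean = rep(NA_real_, k), grow_sd = rep(NA_real_, k),
                    die_mean = rep(NA_real_, k), die_sd = rep(NA_real_, k))
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
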