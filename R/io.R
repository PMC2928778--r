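fmt17 <- function(x) sprintf("%.17g", x)

#' Write a simulation snapshot to a text file
#'
#' Sectioned CSV with a header (config hash, day, clock), per-cell rows and
#' per-point geometry rows (cell id, point index, coordinates, receptor
#' kind, ECM load) plus the adhesion bond table. Doubles are written with 17
#' significant digits so [read_snapshot()] reconstructs the tissue
#' bit-exactly.
#'
#' @param x an `ib_state` or a trajectory snapshot (list with `tissue`,
#'   `clock`, `day`).
#' @param path output file.
#' @param config_hash optional hash stamped into the header.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(x, path, config_hash = "") {
  tis <- x$tissue
  day <- if (!is.null(x$day)) x$day else x$clock / 24
  kind_names <- names(receptor_kinds)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# ibcell snapshot v1",
               sprintf("# config_hash=%s day=%s clock=%s", config_hash,
                       fmt17(day), fmt17(x$clock %||% (day * 24)))), con)
  writeLines("[cells]", con)
  writeLines("cell_id,phenotype,polarized,area_um2,age_h,birth_h,maturation_h,rest_area_um2", con)
  for (cell in tis$cells)
    writeLines(paste(cell$id, cell$phenotype, cell$polarized,
                     fmt17(polygon_area(cell)), fmt17(cell$age),
                     fmt17(cell$birth_time), fmt17(cell$maturation),
                     fmt17(cell$rest_area), sep = ","), con)
  writeLines("[points]", con)
  writeLines("cell_id,point_index,x_um,y_um,receptor_kind,ecm", con)
  for (cell in tis$cells) {
    n <- nrow(cell$xy)
    writeLines(paste(cell$id, seq_len(n), fmt17(cell$xy[, 1]),
                     fmt17(cell$xy[, 2]), kind_names[cell$kind],
                     fmt17(cell$ecm), sep = ","), con)
  }
  writeLines("[bonds]", con)
  writeLines("cell_a,idx_a,cell_b,idx_b,rest", con)
  b <- tis$bonds
  if (nrow(b))
    writeLines(paste(b$cell_a, b$idx_a, b$cell_b, b$idx_b, fmt17(b$rest),
                     sep = ","), con)
  invisible(path)
}

#' Read a snapshot file back into a tissue
#'
#' @param path a file written by [write_snapshot()].
#' @return list with `tissue`, `day`, `clock`, `config_hash`.
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "# ibcell snapshot v1")
    stop("not an ibcell snapshot file: ", path)
  hdr <- regmatches(lines[2],
    regexec("config_hash=(\\S*) day=(\\S+) clock=(\\S+)", lines[2]))[[1]]
  sec <- function(name) {
    i <- which(lines == paste0("[", name, "]"))
    if (!length(i)) stop("snapshot missing section [", name, "]")
    j <- grep("^\\[", lines)
    end <- c(j[j > i], length(lines) + 1)[1] - 1
    if (end <= i + 1) return(NULL)
    txt <- lines[(i + 1):end]
    nfield <- utils::count.fields(textConnection(txt), sep = ",")
    if (any(nfield != nfield[1]))
      stop("corrupted snapshot row at line ",
           i + 1 + which(nfield != nfield[1])[1])
    out <- tryCatch(
      utils::read.csv(text = txt, stringsAsFactors = FALSE),
      error = function(e) stop("corrupted snapshot section [", name,
                               "] near line ", i + 1, ": ",
                               conditionMessage(e)))
    out
  }
  cells_df <- sec("cells")
  pts <- sec("points")
  bonds <- sec("bonds")
  cells <- list()
  for (r in seq_len(nrow(cells_df))) {
    id <- cells_df$cell_id[r]
    p <- pts[pts$cell_id == id, , drop = FALSE]
    p <- p[order(p$point_index), , drop = FALSE]
    cell <- new_cell(id, c(0, 0), n_points = nrow(p),
                     rest_area = cells_df$rest_area_um2[r],
                     birth_time = cells_df$birth_h[r],
                     maturation = cells_df$maturation_h[r])
    cell$xy <- cbind(p$x_um, p$y_um)
    cell$kind <- unname(receptor_kinds[p$receptor_kind])
    cell$ecm <- p$ecm
    cell$phenotype <- cells_df$phenotype[r]
    cell$polarized <- as.logical(cells_df$polarized[r])
    cell$age <- cells_df$age_h[r]
    cells[[length(cells) + 1]] <- cell
  }
  tis <- tissue(cells)
  if (!is.null(bonds) && nrow(bonds)) tis$bonds <- bonds
  list(tissue = tis, day = as.numeric(hdr[3]), clock = as.numeric(hdr[4]),
       config_hash = hdr[2])
}

receptor_palette <- c(
  growth_sensor = "#2c5aa0",    # blue
  adhesion_receptor = "#2ca02c",# green
  ecm_receptor = "#e66101",     # pink-red-orange base (shaded by ECM load)
  apical_marker = "#00c8c8",    # cyan
  death_receptor = "#8c8c8c"    # grey
)

nucleus_palette <- c(viable = "#2c5aa0", growing = "#2ca02c",
                     dying = "#d62728")

#' Render a snapshot
#'
#' Draws cell outlines with boundary points coloured by receptor kind
#' (adhesion green, growth sensors blue, ECM receptors pink-red-orange
#' shaded by local ECM concentration, apical markers cyan, death receptors
#' grey) and a nucleus dot per cell coloured viable blue / growing green /
#' dying red. The device is chosen by the file extension (pdf, png or svg).
#' Rendering never mutates the state.
#'
#' @param x an `ib_state` or trajectory snapshot.
#' @param path output image path.
#' @param xlim,ylim optional view window, um.
#' @return `path`, invisibly.
#' @export
render_snapshot <- function(x, path, xlim = NULL, ylim = NULL) {
  tis <- x$tissue
  allxy <- do.call(rbind, lapply(tis$cells, `[[`, "xy"))
  pad <- 5
  if (is.null(xlim)) xlim <- range(allxy[, 1]) + c(-pad, pad)
  if (is.null(ylim)) ylim <- range(allxy[, 2]) + c(-pad, pad)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = grDevices::png(path, 800, 800),
         svg = grDevices::svg(path, 7, 7),
         grDevices::pdf(path, 7, 7))
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(2, 2, 1, 1))
  graphics::plot(NA, xlim = xlim, ylim = ylim, asp = 1, xlab = "", ylab = "",
                 main = sprintf("day %.1f", (x$clock %||% 0) / 24))
  ecm_ramp <- grDevices::colorRamp(c("#f7c6d9", "#e03131", "#e8590c"))
  for (cell in tis$cells) {
    graphics::polygon(cell$xy[, 1], cell$xy[, 2], border = "grey70",
                      col = NA)
    cols <- receptor_palette[names(receptor_kinds)[cell$kind]]
    is_ecm <- cell$kind == receptor_kinds[["ecm_receptor"]]
    if (any(is_ecm)) {
      load <- pmin(1, cell$ecm[is_ecm] / max(cell$ecm[is_ecm], 1))
      rgbm <- ecm_ramp(load)
      cols[is_ecm] <- grDevices::rgb(rgbm[, 1], rgbm[, 2], rgbm[, 3],
                                     maxColorValue = 255)
    }
    graphics::points(cell$xy[, 1], cell$xy[, 2], col = cols, pch = 16,
                     cex = 0.4)
    ctr <- polygon_centroid(cell$xy)
    ncol <- if (cell$phenotype %in% c("growing", "dividing"))
      nucleus_palette[["growing"]]
    else if (cell$phenotype == "apoptotic") nucleus_palette[["dying"]]
    else nucleus_palette[["viable"]]
    graphics::points(ctr[1], ctr[2], col = ncol, pch = 16, cex = 1.5)
  }
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce an invocation: the full
#' configuration, package version, fixture checksums, and the list of
#' output files.
#'
#' @param config an `ib_config`.
#' @param out_files character vector of produced files.
#' @param path manifest path (YAML).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, out_files, path) {
  yaml::write_yaml(list(
    package = "ibcell",
    version = as.character(utils::packageVersion("ibcell")),
    config = unclass(config),
    config_hash = config_hash(config),
    fixture_checksums = as.list(fixture_checksums()),
    outputs = as.list(out_files)
  ), path)
  invisible(path)
}
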