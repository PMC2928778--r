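#' Sweep the threshold space into a morphochart
#'
#' Runs one deterministic simulation per vertex of the `(G, D, E)` grid and
#' classifies the final morphology, mapping out which threshold
#' combinations give normal hollow acini, filled or degenerate structures,
#' and non-stabilized (mutant-like) growth.
#'
#' @param base_config an [sim_config()]; thresholds are overridden per
#'   vertex, everything else is shared.
#' @param G_list,D_list,E_list axis values (percent, percent, density).
#' @param quiet suppress per-run progress.
#' @return an object of class `ib_morphochart`: a data frame of vertices
#'   with class and final counts, plus the axes as attributes.
#' @export
morphochart_sweep <- function(base_config, G_list, D_list, E_list,
                              quiet = TRUE) {
  G_list <- sort(unique(G_list)); D_list <- sort(unique(D_list))
  E_list <- sort(unique(E_list))
  grid <- expand.grid(G = G_list, D = D_list, E = E_list,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    cfg <- base_config
    cfg$G <- grid$G[r]; cfg$D <- grid$D[r]; cfg$E <- grid$E[r]
    cfg <- validate_config(unclass(cfg))
    traj <- run_simulation(cfg)
    cnt <- utils::tail(traj$counts, 1)
    if (!quiet)
      message(sprintf("V=(%g,%g,%g): %s, %d cells", grid$G[r], grid$D[r],
                      grid$E[r], classify_morphology(traj), cnt$n_total))
    data.frame(G = grid$G[r], D = grid$D[r], E = grid$E[r],
               class = classify_morphology(traj),
               n_total = cnt$n_total, n_growing = cnt$n_growing,
               n_dying = cnt$n_dying,
               stabilized = traj$stabilized,
               config_hash = traj$config_hash)
  })
  chart <- do.call(rbind, rows)
  attr(chart, "axes") <- list(G = G_list, D = D_list, E = E_list)
  class(chart) <- c("ib_morphochart", class(chart))
  chart
}

#' Locate a morphology class in a morphochart
#'
#' @param chart an `ib_morphochart`.
#' @param morph_class one of the four class labels.
#' @return list with the member `vertices` and their axis-aligned `hull`
#'   (per-axis range), both empty when the class is absent.
#' @export
locate_region <- function(chart, morph_class) {
  v <- chart[chart$class == morph_class, c("G", "D", "E"), drop = FALSE]
  hull <- if (nrow(v)) lapply(v, range) else list()
  list(vertices = v, hull = hull)
}

#' Default tuning menu
#'
#' The parameter perturbations explored by the search tree, mirroring the
#' biological knobs that matter at each developmental stage: early
#' checkpoints are fitted with proliferation parameters (adhesion contact
#' range, maturation time, fluid source strength, growth threshold), later
#' checkpoints with death, polarization and ECM-arrest parameters.
#'
#' @return data frame with columns `key`, `stage`, `kind`, `step`.
#' @export
default_parameter_menu <- function() {
  data.frame(
    key = c("d_contact_um", "maturation_h", "source_strength", "G",
            "D", "E", "apical_delay_h", "death_delay_h"),
    stage = c("early", "early", "early", "early",
              "late", "late", "late", "late"),
    kind = c("rel", "rel", "rel", "abs", "abs", "abs", "rel", "rel"),
    step = c(0.2, 0.2, 0.2, 2.5, 2.5, 0.5, 0.2, 0.2)
  )
}

menu_variants <- function(config, menu_row) {
  key <- menu_row$key
  base <- config[[key]]
  vals <- if (menu_row$kind == "rel")
    base * c(1 - menu_row$step, 1 + menu_row$step)
  else base + c(-menu_row$step, menu_row$step)
  if (key %in% c("G", "D")) vals <- pmin(100, pmax(0, vals))
  if (key %in% c("E", "maturation_h", "apical_delay_h", "death_delay_h"))
    vals <- pmax(0, vals)
  vals <- unique(vals[vals != base | FALSE])
  lapply(vals, function(v) {
    cfg <- config; cfg[[key]] <- v
    list(config = validate_config(unclass(cfg)),
         label = sprintf("%s=%g", key, v))
  })
}

#' Tune a configuration against per-day count targets (search tree)
#'
#' Stagewise pruned search: at each checkpoint day, every surviving node
#' branches over the applicable menu perturbations (plus keeping its
#' parameters), each branch is re-simulated from a single cell at day 0 up
#' to the checkpoint, and only branches whose counts fall within one
#' standard deviation of the experimental mean at every checkpoint reached
#' survive; survivors are ranked by worst z-score and truncated to
#' `beam_width`. Early checkpoints branch over proliferation parameters,
#' later ones over death/polarization/ECM parameters. Fully deterministic
#' given the menu order and beam width.
#'
#' @param base_config starting [sim_config()].
#' @param target_table data frame with `day`, `total_mean`, `total_sd` and
#'   optional `grow_mean`/`grow_sd`, `die_mean`/`die_sd` columns.
#' @param parameter_menu see [default_parameter_menu()].
#' @param beam_width surviving nodes kept per stage.
#' @param quiet suppress progress.
#' @return list with `success`, the best node's `config`, its perturbation
#'   `path`, the per-checkpoint `fit` table of the best node, and for
#'   failures a `nearest_miss` diagnostic.
#' @export
tune_thresholds <- function(base_config, target_table,
                            parameter_menu = default_parameter_menu(),
                            beam_width = 4, quiet = TRUE) {
  stopifnot(nrow(target_table) >= 1)
  days <- sort(unique(target_table$day))
  target_table <- target_table[order(target_table$day), , drop = FALSE]
  cache <- new.env(parent = emptyenv())
  eval_node <- function(config, upto_day) {
    key <- paste(config_hash(config), upto_day)
    if (!is.null(cache[[key]])) return(cache[[key]])
    cfg <- config
    cfg$t_end_days <- upto_day
    cfg$day_schedule <- days[days <= upto_day]
    cfg <- validate_config(unclass(cfg))
    traj <- run_simulation(cfg)
    fit <- compare_to_targets(traj$counts,
                              target_table[target_table$day <= upto_day, ,
                                           drop = FALSE])
    res <- list(fit = fit, max_z = attr(fit, "max_abs_z"),
                ok = all(fit$within_band %in% TRUE))
    cache[[key]] <- res
    res
  }
  nodes <- list(list(config = base_config, path = "base"))
  best_miss <- NULL
  for (k in seq_along(days)) {
    stage <- if (k <= ceiling(length(days) / 2)) "early" else "late"
    menu <- parameter_menu[parameter_menu$stage == stage, , drop = FALSE]
    cand <- list()
    for (nd in nodes) {
      cand[[length(cand) + 1]] <- nd
      for (m in seq_len(nrow(menu))) {
        for (v in menu_variants(nd$config, menu[m, ])) {
          cand[[length(cand) + 1]] <-
            list(config = v$config, path = paste(nd$path, v$label, sep = " -> "))
        }
      }
    }
    scored <- lapply(cand, function(nd) {
      r <- eval_node(nd$config, days[k])
      c(nd, r)
    })
    for (s in scored) {
      if (is.null(best_miss) || (is.finite(s$max_z) &&
                                 s$max_z < best_miss$max_z)) best_miss <- s
    }
    keep <- Filter(function(s) isTRUE(s$ok), scored)
    if (!length(keep)) {
      return(list(success = FALSE, config = NULL, path = NULL,
                  fit = NULL,
                  nearest_miss = list(path = best_miss$path,
                                      max_abs_z = best_miss$max_z,
                                      fit = best_miss$fit)))
    }
    ord <- order(vapply(keep, function(s) s$max_z, 0))
    nodes <- lapply(keep[ord[seq_len(min(beam_width, length(keep)))]],
                    function(s) list(config = s$config, path = s$path))
    if (!quiet)
      message(sprintf("day %g: %d candidates, %d survive", days[k],
                      length(cand), length(nodes)))
  }
  best <- nodes[[1]]
  final <- eval_node(best$config, days[length(days)])
  list(success = TRUE, config = best$config, path = best$path,
       fit = final$fit, n_surviving = length(nodes))
}
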