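#' Phenotype counts of a snapshot
#'
#' Totals over live cells: growing and dividing cells count as growing
#' (proliferating, the Ki67 analogue), apoptotic cells as dying (the
#' caspase-3 analogue).
#'
#' @param x an `ib_state`, a trajectory snapshot, or an `ib_tissue`.
#' @return named integer vector `n_total`, `n_growing`, `n_dying`.
#' @export
count_phenotypes <- function(x) {
  tis <- if (inherits(x, "ib_tissue")) x else x$tissue
  ph <- vapply(tis$cells, `[[`, "", "phenotype")
  c(n_total = length(ph),
    n_growing = sum(ph %in% c("growing", "dividing")),
    n_dying = sum(ph == "apoptotic"))
}

#' Cluster, lumen and monolayer measurements
#'
#' Rasterizes the cell polygons at half the fluid mesh width, flood-fills
#' the exterior from the box edge, and reports: `cluster_area` (cells plus
#' any enclosed cavity), `lumen_area` (enclosed cell-free region, with
#' sub-resolution slivers below 5 percent of the mean cell area ignored),
#' and `monolayer` (every live cell owns at least one basal point).
#'
#' @param tissue an `ib_tissue`.
#' @param config the run's `ib_config`.
#' @return list with `cluster_area_um2`, `lumen_area_um2`, `monolayer`,
#'   `roundness`.
#' @export
cluster_metrics <- function(tissue, config) {
  if (!n_cells(tissue)) stop("empty tissue")
  n <- 2L * config$grid_n
  hm <- config$domain_um / n
  mask <- matrix(0L, n, n)
  for (cell in tissue$cells)
    rasterize_polygon_cpp(mask, cell$xy[, 1], cell$xy[, 2], 0, 0, hm)
  lab <- flood_exterior_cpp(mask)
  cell_px <- sum(lab == 1L)
  lumen_px <- sum(lab == 0L)
  areas <- vapply(tissue$cells, polygon_area, 0)
  lumen_area <- lumen_px * hm^2
  if (lumen_area < 0.05 * mean(areas)) lumen_area <- 0
  cls <- classify_points(tissue, config)
  monolayer <- all(cls$outer)
  cluster_area <- (cell_px + lumen_px) * hm^2
  list(cluster_area_um2 = cluster_area,
       lumen_area_um2 = lumen_area,
       monolayer = monolayer,
       roundness = cluster_roundness(tissue, cls, cluster_area))
}

# scale-invariant roundness in [0, 1]: isoperimetric circularity of the
# convex hull of all boundary points times the solidity (cluster area over
# hull area). A compact round acinus scores near 1; elongated outlines
# lower the first factor, lobed or branched ones the second.
cluster_roundness <- function(tissue, cls, cluster_area) {
  pts <- do.call(rbind, lapply(tissue$cells, `[[`, "xy"))
  if (is.null(pts) || nrow(pts) < 8) return(1)
  hull <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
  a_hull <- abs(shoelace(hull))
  per <- sum(sqrt(rowSums((hull - hull[c(2:nrow(hull), 1), ,
                                       drop = FALSE])^2)))
  if (a_hull <= 0 || per <= 0) return(1)
  min(1, 4 * pi * a_hull / per^2) * min(1, cluster_area / a_hull)
}

#' Equivalent cell diameter from cross-section area and count
#'
#' `2 * sqrt(area / (n * pi))`: the diameter of `n` equal circles tiling the
#' measured cross-section area.
#'
#' @param total_area_um2 cross-section area, um^2.
#' @param n_cells cell count in the section.
#' @return diameter, um (vectorized).
#' @export
equivalent_diameter <- function(total_area_um2, n_cells) {
  2 * sqrt(total_area_um2 / (n_cells * pi))
}

#' Four-class morphology of a finished run
#'
#' `non_stabilized` if the structure was still growing or dividing at the
#' final time; otherwise `normal` for a round hollow monolayer, `filled` for
#' a stabilized structure without lumen or with a multilayer, `degenerate`
#' for a stabilized but distorted outline (roundness below `rho_min`).
#'
#' @param trajectory an `ib_trajectory`.
#' @param rho_min minimum isoperimetric roundness for the normal class.
#' @return one of `"normal"`, `"filled"`, `"degenerate"`, `"non_stabilized"`.
#' @export
classify_morphology <- function(trajectory, rho_min = 0.75) {
  last <- trajectory$snapshots[[length(trajectory$snapshots)]]
  if (!n_cells(last$tissue))
    stop(ibcell_condition("ibcell_geometry_defect",
                          "cannot classify an empty tissue"))
  if (!trajectory$stabilized) return("non_stabilized")
  m <- cluster_metrics(last$tissue, trajectory$config)
  if (m$monolayer && m$lumen_area_um2 > 0 && m$roundness >= rho_min)
    return("normal")
  if (m$lumen_area_um2 == 0 || !m$monolayer) return("filled")
  "degenerate"
}

#' Compare simulated counts to an experimental target table
#'
#' Per checkpoint day, tests whether each simulated count lies within one
#' standard deviation of the experimental mean, and reports z-scores.
#' Columns with `NA` mean or zero/`NA` SD are skipped.
#'
#' @param count_series data frame with `day`, `n_total`, and optionally
#'   `n_growing`, `n_dying` (as produced by [run_simulation()]).
#' @param target_table data frame with `day`, `total_mean`, `total_sd`, and
#'   optionally `grow_mean`, `grow_sd`, `die_mean`, `die_sd`.
#' @return data frame per checkpoint with `within_band` and `max_abs_z`,
#'   plus the overall `max_abs_z` as an attribute.
#' @export
compare_to_targets <- function(count_series, target_table) {
  stopifnot(all(c("day", "total_mean", "total_sd") %in% names(target_table)))
  specs <- list(c("n_total", "total_mean", "total_sd"),
                c("n_growing", "grow_mean", "grow_sd"),
                c("n_dying", "die_mean", "die_sd"))
  out <- lapply(seq_len(nrow(target_table)), function(r) {
    day <- target_table$day[r]
    sim <- count_series[count_series$day == day, , drop = FALSE]
    if (!nrow(sim))
      return(data.frame(day = day, within_band = NA, max_abs_z = NA_real_))
    zs <- c()
    for (sp in specs) {
      if (!sp[2] %in% names(target_table) || !sp[1] %in% names(sim)) next
      mu <- target_table[[sp[2]]][r]
      sd <- target_table[[sp[3]]][r]
      if (is.na(mu) || is.na(sd) || sd <= 0) next
      zs <- c(zs, (sim[[sp[1]]][1] - mu) / sd)
    }
    if (!length(zs))
      return(data.frame(day = day, within_band = NA, max_abs_z = NA_real_))
    data.frame(day = day, within_band = all(abs(zs) <= 1),
               max_abs_z = max(abs(zs)))
  })
  res <- do.call(rbind, out)
  attr(res, "max_abs_z") <- suppressWarnings(max(res$max_abs_z, na.rm = TRUE))
  res
}
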