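#' Initialize a simulation state
#'
#' One daughter-sized circular cell (area = rest area; the cell divides at
#' twice this) centred in the periodic box; ECM zero; clock at day 0.
#'
#' @param config an [sim_config()] object.
#' @return an object of class `ib_state`.
#' @export
init_state <- function(config) {
  stopifnot(inherits(config, "ib_config"))
  grid <- fluid_grid(config$grid_n, config$domain_um, config$mu, config$rho)
  rest_area <- pi * config$cell_diameter_um^2 / 4   # daughter/resting area
  cell <- new_cell(1L, rep(config$domain_um / 2, 2), area = rest_area,
                   n_points = config$n_points_init, rest_area = rest_area,
                   birth_time = 0, maturation = 0)
  tis <- tissue(list(cell))
  state <- list(
    config = config, grid = grid, tissue = tis,
    clock = 0, steps = 0L,
    cls = classify_points(tis, config),
    last_activity = 0,
    events = list(),
    aborted = NULL
  )
  class(state) <- "ib_state"
  state
}

#' @export
print.ib_state <- function(x, ...) {
  cat(sprintf("<ib_state> t = %.2f h (day %.2f), %d cells, %d bonds\n",
              x$clock, x$clock / 24, n_cells(x$tissue), nrow(x$tissue$bonds)))
  invisible(x)
}

record_event <- function(state, type, ...) {
  state$events[[length(state$events) + 1]] <-
    c(list(time = state$clock, type = type), list(...))
  state
}

#' Advance the simulation by one time step
#'
#' Fixed sub-step order so decisions always act on fresh receptor state:
#' at the rule cadence, (1) splits and resampling, (2) receptor updates
#' (adhesion, ECM receptors, polarization, death receptors), (3) phenotype
#' decisions (growth, apoptosis, division trigger); every step, (4) balanced
#' source/sink placement, (5) force assembly and spreading, (6) fluid solve,
#' (7) velocity interpolation and advection (with adaptive halving so no
#' boundary point moves more than h/4), (8) ECM kinetics and clock updates.
#' The step is a pure function of the state, and the model contains no
#' random element, so identical configurations replay identically.
#'
#' @param state an `ib_state`.
#' @return the advanced state.
#' @export
sim_step <- function(state) {
  cfg <- state$config
  rule_every <- max(1L, as.integer(round(cfg$rule_dt_h / cfg$dt_h)))
  if (state$steps %% rule_every == 0L)
    state <- rule_phase(state, rule_dt = rule_every * cfg$dt_h)
  state <- mech_phase(state, cfg$dt_h, depth = 0L)
  state$steps <- state$steps + 1L
  state
}

rule_phase <- function(state, rule_dt) {
  cfg <- state$config
  tis <- state$tissue
  # (1) geometric splits of fully pinched dividing cells
  split_tol <- 2 * cfg$spacing_um
  for (id in names(tis$cells)) {
    cell <- tis$cells[[id]]
    if (!identical(cell$phenotype, "dividing") || is.null(cell$ring)) next
    d <- sqrt(sum((cell$xy[cell$ring[2], ] - cell$xy[cell$ring[1], ])^2))
    overdue <- !is.null(cell$division_clock) &&
      cell$division_clock >= cfg$max_division_h
    if (d <= split_tol || overdue) {
      daughters <- tryCatch(
        split_cell(cell, tis$next_id, now = state$clock,
                   maturation = cfg$maturation_h,
                   spacing = cfg$spacing_um),
        ibcell_geometry_defect = function(e) NULL)
      if (is.null(daughters)) {
        # neck not cleanly separable yet; keep contracting unless hopeless
        if (!is.null(cell$division_clock) &&
            cell$division_clock > 2 * cfg$max_division_h)
          stop(ibcell_condition("ibcell_geometry_defect", sprintf(
            "cell %d cannot be split", cell$id)))
        next
      }
      rows <- which(tis$bonds$cell_a == cell$id | tis$bonds$cell_b == cell$id)
      tis <- disassemble_bonds(tis, rows, death_fate = FALSE)
      tis$cells[[id]] <- NULL
      for (d2 in daughters) tis <- set_cell(tis, d2)
      tis$next_id <- tis$next_id + 2L
      state$tissue <- tis
      state <- record_event(state, "division", cell_id = cell$id,
                            birth = cell$birth_time,
                            cycle_h = state$clock - cell$birth_time,
                            daughters = paste(vapply(daughters, `[[`, 0L, "id"),
                                              collapse = "+"))
      state$last_activity <- state$clock
      tis <- state$tissue
    }
  }
  # (1a) remove any cell crushed below the viability floor (dying cells are
  # handled by the apoptosis rule; this catches mechanically collapsed ones)
  for (id in names(tis$cells)) {
    cell <- tis$cells[[id]]
    if (polygon_area(cell) < 0.1 * cell$rest_area) {
      rows <- which(tis$bonds$cell_a == cell$id | tis$bonds$cell_b == cell$id)
      tis <- disassemble_bonds(tis, rows, death_fate = TRUE, cls = state$cls)
      tis$removed_log <- rbind(tis$removed_log,
                               data.frame(time = state$clock,
                                          cell_id = cell$id,
                                          area = polygon_area(cell)))
      tis$cells[[id]] <- NULL
      state <- record_event(state, "removal", cell_id = cell$id)
    }
  }
  # (1b) boundary resampling, protecting bonded and ring points
  for (id in names(tis$cells)) {
    cell <- tis$cells[[id]]
    prot <- c(tis$bonds$idx_a[tis$bonds$cell_a == cell$id],
              tis$bonds$idx_b[tis$bonds$cell_b == cell$id],
              cell$ring)
    res <- resample_boundary(cell, cfg$spacing_um, protect = as.integer(prot))
    map <- res$map
    newc <- res$cell
    if (polygon_self_intersects_cpp(newc$xy[, 1], newc$xy[, 2])) {
      fixed <- untangle_cell(newc)
      if (is.null(fixed)) {
        if (identical(newc$phenotype, "apoptotic")) {
          # a draining cell crumpled beyond repair: treat as fully drained
          rows <- which(tis$bonds$cell_a == cell$id |
                        tis$bonds$cell_b == cell$id)
          tis <- disassemble_bonds(tis, rows, death_fate = TRUE,
                                   cls = state$cls)
          tis$removed_log <- rbind(tis$removed_log,
                                   data.frame(time = state$clock,
                                              cell_id = cell$id,
                                              area = polygon_area(newc)))
          tis$cells[[id]] <- NULL
          state <- record_event(state, "removal", cell_id = cell$id)
          next
        }
        stop(ibcell_condition("ibcell_geometry_defect", sprintf(
          "cell %d membrane could not be untangled", cell$id)))
      }
      kept <- attr(fixed, "kept")
      map <- match(map, kept)            # NA for dropped points
      if (!is.null(newc$ring)) {
        ring2 <- match(newc$ring, kept)
        fixed$ring <- if (any(is.na(ring2)) || ring2[1] == ring2[2]) NULL
                      else as.integer(ring2)
        if (is.null(fixed$ring) &&
            identical(fixed$phenotype, "dividing")) {
          fixed$phenotype <- "growing"   # ring lost; re-trigger later
          fixed$rest_ring <- NA_real_
        }
      }
      newc <- fixed
    }
    if (!identical(map, seq_len(nrow(cell$xy))) ||
        nrow(newc$xy) != nrow(cell$xy)) {
      ra <- which(tis$bonds$cell_a == cell$id)
      rb <- which(tis$bonds$cell_b == cell$id)
      tis$bonds$idx_a[ra] <- map[tis$bonds$idx_a[ra]]
      tis$bonds$idx_b[rb] <- map[tis$bonds$idx_b[rb]]
      lost <- union(ra[is.na(tis$bonds$idx_a[ra])],
                    rb[is.na(tis$bonds$idx_b[rb])])
      if (length(lost))
        tis <- disassemble_bonds(tis, lost, death_fate = FALSE)
    }
    tis <- set_cell(tis, newc)
  }
  # seam guard: the spectral solver is periodic, so the tissue must stay
  # clear of the wrap
  allxy <- do.call(rbind, lapply(tis$cells, `[[`, "xy"))
  m <- cfg$seam_margin_um
  if (any(allxy < m) || any(allxy > cfg$domain_um - m))
    stop(ibcell_condition("ibcell_seam",
      "tissue reached the periodic wrap seam; enlarge domain_um"))
  # (2) receptor updates on fresh geometry
  cls <- classify_points(tis, cfg)
  tis <- update_adhesion(tis, cfg$d_contact_um, cfg$d_break_um,
                         cfg$bond_rest_um, cls = cls)
  tis <- update_ecm_receptors(tis, cfg$E)
  for (id in names(tis$cells)) {
    if (isTRUE(cls$outer[[id]])) {
      tis$cells[[id]]$last_outer <- state$clock
    }
  }
  tis <- update_polarization(tis, cfg$apical_delay_h, cls, rule_dt,
                             now = state$clock)
  tis <- update_death_receptors(tis, cls, now = state$clock)
  # (3) phenotype decisions
  flags <- list(lumen_sensing = cfg$lumen_sensing,
                contact_inhibition_released = cfg$contact_inhibition_released)
  for (id in names(tis$cells)) {
    cell <- tis$cells[[id]]
    if (cell$phenotype %in% c("apoptotic", "dividing")) next
    if (cell$maturation > 0) {
      cell$phenotype <- "resting"
    } else {
      cell$phenotype <- if (decide_growth(cell, cfg$G, flags) == "growing")
        "growing" else "resting"
    }
    tis <- set_cell(tis, cell)
  }
  n_before <- n_cells(tis)
  tis <- update_apoptosis(tis, cfg$D, cfg$death_delay_h, cfg$detach_delay_h,
                          cls = cls, rule_dt = rule_dt, now = state$clock)
  if (n_cells(tis) < n_before) {
    gone <- utils::tail(tis$removed_log, n_before - n_cells(tis))
    for (r in seq_len(nrow(gone)))
      state <- record_event(state, "removal", cell_id = gone$cell_id[r])
  }
  for (id in names(tis$cells)) {
    cell <- tis$cells[[id]]
    cell2 <- check_division(cell, n_cells(tis), cfg$division_mode_switch,
                            basal = cls$basal[[id]] %||%
                              rep(FALSE, nrow(cell$xy)))
    if (!identical(cell2$phenotype, cell$phenotype))
      tis <- set_cell(tis, cell2)
  }
  state$tissue <- tis
  state$cls <- cls
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flatten the tissue into one point table for force spreading / advection
flatten_tissue <- function(tis) {
  ids <- names(tis$cells)
  sizes <- vapply(tis$cells, function(c) nrow(c$xy), 0L)
  off <- stats::setNames(c(0L, cumsum(sizes))[seq_along(ids)], ids)
  xy <- do.call(rbind, lapply(tis$cells, `[[`, "xy"))
  list(xy = xy, offset = off, sizes = sizes, ids = ids)
}

assemble_forces <- function(tis, flat, cfg) {
  F <- matrix(0, nrow(flat$xy), 2)
  for (id in flat$ids) {
    cell <- tis$cells[[id]]
    rows <- flat$offset[[id]] + seq_len(nrow(cell$xy))
    F[rows, ] <- F[rows, ] + membrane_forces(cell, cfg$k_membrane,
                                             cfg$spacing_um)
    if (identical(cell$phenotype, "dividing"))
      F[rows, ] <- F[rows, ] + contractile_forces(cell, cfg$k_ring)
  }
  b <- tis$bonds
  if (nrow(b)) {
    ia <- flat$offset[as.character(b$cell_a)] + b$idx_a
    ib <- flat$offset[as.character(b$cell_b)] + b$idx_b
    d <- flat$xy[ib, , drop = FALSE] - flat$xy[ia, , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    len[len == 0] <- 1
    f <- d * (cfg$k_adhesion * (len - b$rest) / len)
    # each point carries at most one bond, so indices are collision-free
    F[ia, ] <- F[ia, ] + f
    F[ib, ] <- F[ib, ] - f
  }
  F
}

assemble_sources <- function(tis, cfg, h, cls = NULL) {
  pos <- list(); str <- list()
  flags <- list(lumen_sensing = cfg$lumen_sensing,
                contact_inhibition_released = cfg$contact_inhibition_released)
  for (cell in tis$cells) {
    if (identical(cell$phenotype, "growing")) {
      offset <- min(2.5 * h, 0.4 * sqrt(polygon_area(cell) / pi))
      open <- cls$open[[as.character(cell$id)]]
      if (is.null(open) || length(open) != nrow(cell$xy))
        open <- rep(TRUE, nrow(cell$xy))
      s <- place_growth_sources(cell, cfg$source_strength, offset, flags,
                                open = open)
    } else if (identical(cell$phenotype, "apoptotic")) {
      offset <- min(2.5 * h, 0.4 * sqrt(polygon_area(cell) / pi))
      s <- apoptotic_sources(cell, cfg$apoptosis_rate, offset)
    } else next
    if (length(s$strength)) {
      pos[[length(pos) + 1]] <- s$positions
      str[[length(str) + 1]] <- s$strength
    }
  }
  if (!length(pos))
    return(list(positions = matrix(numeric(), 0, 2), strength = numeric()))
  list(positions = do.call(rbind, pos), strength = unlist(str))
}

mech_phase <- function(state, dt, depth) {
  cfg <- state$config
  tis <- state$tissue
  flat <- flatten_tissue(tis)
  F <- assemble_forces(tis, flat, cfg)
  src <- assemble_sources(tis, cfg, state$grid$h, cls = state$cls)
  grid <- state$grid
  grid <- spread(grid, flat$xy, F, target = "force", reset = TRUE)
  if (nrow(src$positions)) {
    grid <- spread(grid, src$positions, src$strength, target = "source",
                   reset = TRUE)
  } else grid$s[] <- 0
  grid <- solve_fluid_step(grid, dt)
  vel <- interpolate_velocity(grid, flat$xy)
  maxd <- if (nrow(vel)) max(abs(vel)) * dt else 0
  if (maxd > grid$h / 4 && depth < 3L) {
    state$grid <- grid
    state <- mech_phase(state, dt / 2, depth + 1L)
    state <- mech_phase(state, dt / 2, depth + 1L)
    return(state)
  }
  newxy <- advect(flat$xy, vel, dt, grid, warn = FALSE)
  dimnames(newxy) <- NULL
  grew <- any(src$strength > 0)
  for (id in flat$ids) {
    cell <- tis$cells[[id]]
    rows <- flat$offset[[id]] + seq_len(nrow(cell$xy))
    cell$xy <- newxy[rows, , drop = FALSE]
    cell$age <- cell$age + dt
    cell$maturation <- max(0, cell$maturation - dt)
    if (identical(cell$phenotype, "dividing")) {
      cell$rest_ring <- max(0, cell$rest_ring - cfg$ring_rate_um_h * dt)
      cell$division_clock <- (cell$division_clock %||% 0) + dt
    }
    tis <- set_cell(tis, cell)
  }
  tis <- update_ecm_field(tis, cfg$ecm_secretion, cfg$ecm_decay, dt,
                          basal = state$cls$basal)
  state$tissue <- tis
  state$grid <- grid
  state$clock <- state$clock + dt
  if (grew) state$last_activity <- state$clock
  state
}

#' Growth-arrest (stabilization) check
#'
#' A structure is stabilized when no cell has grown (placed fluid sources)
#' or divided during the trailing window. The property is absorbing under
#' unchanged inputs because arrested cells place no sources.
#'
#' @param state an `ib_state`.
#' @param window_days trailing window, days.
#' @return logical.
#' @export
check_stabilization <- function(state, window_days = 2) {
  state$clock - state$last_activity >= window_days * 24
}

#' Run a full simulation
#'
#' Advances from a single cell to `t_end_days`, capturing day-indexed
#' snapshots. Stabilized runs stop after a grace window; their remaining
#' scheduled snapshots repeat the frozen final state (nothing can change any
#' more by construction of the rules).
#'
#' @param config an [sim_config()] object.
#' @param quiet suppress progress messages.
#' @return an object of class `ib_trajectory` with `snapshots` (by day),
#'   a per-day `counts` data frame, the event log, and stabilization info.
#' @export
run_simulation <- function(config, quiet = TRUE) {
  state <- init_state(config)
  schedule <- config$day_schedule
  snaps <- list()
  take <- function(state, day) {
    list(day = day, clock = state$clock,
         tissue = state$tissue,
         counts = count_phenotypes(state))
  }
  pending <- schedule
  while (length(pending) && pending[1] * 24 <= state$clock + 1e-9) {
    snaps[[as.character(pending[1])]] <- take(state, pending[1])
    pending <- pending[-1]
  }
  t_end_h <- config$t_end_days * 24
  stabilized_at <- NA_real_
  while (state$clock < t_end_h - 1e-9) {
    state <- sim_step(state)
    while (length(pending) && pending[1] * 24 <= state$clock + 1e-9) {
      snaps[[as.character(pending[1])]] <- take(state, pending[1])
      pending <- pending[-1]
    }
    if (check_stabilization(state, config$stabilization_window_days)) {
      if (is.na(stabilized_at))
        stabilized_at <- state$last_activity +
          config$stabilization_window_days * 24
      if (state$clock >= stabilized_at + config$grace_days * 24 ||
          state$clock >= t_end_h) {
        for (d in pending) snaps[[as.character(d)]] <- take(state, d)
        pending <- numeric()
        break
      }
    } else stabilized_at <- NA_real_
    if (!quiet && state$steps %% 200 == 0)
      message(sprintf("day %.2f: %d cells", state$clock / 24,
                      n_cells(state$tissue)))
  }
  for (d in pending) snaps[[as.character(d)]] <- take(state, d)
  counts <- do.call(rbind, lapply(snaps, function(s)
    data.frame(day = s$day, n_total = s$counts["n_total"],
               n_growing = s$counts["n_growing"],
               n_dying = s$counts["n_dying"])))
  rownames(counts) <- NULL
  counts <- counts[order(counts$day), , drop = FALSE]
  ev <- events_frame(state$events)
  traj <- list(
    config = config, config_hash = config_hash(config),
    snapshots = snaps, counts = counts, events = ev,
    stabilized = !is.na(stabilized_at) &&
      check_stabilization(state, config$stabilization_window_days),
    stabilized_at_h = stabilized_at,
    final_clock_h = state$clock,
    final_state = state
  )
  class(traj) <- "ib_trajectory"
  traj
}

events_frame <- function(events) {
  if (!length(events))
    return(data.frame(time = numeric(), type = character(),
                      cell_id = integer(), cycle_h = numeric()))
  do.call(rbind, lapply(events, function(e)
    data.frame(time = e$time, type = e$type,
               cell_id = e$cell_id %||% NA_integer_,
               cycle_h = e$cycle_h %||% NA_real_)))
}

#' @export
print.ib_trajectory <- function(x, ...) {
  cat(sprintf("<ib_trajectory> %d snapshot days, final %d cells, %s\n",
              length(x$snapshots),
              utils::tail(x$counts$n_total, 1),
              if (x$stabilized) sprintf("stabilized (day %.1f)",
                                        x$stabilized_at_h / 24)
              else "non-stabilized"))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Mean inter-division (effective doubling) time of a run
#'
#' Average over all recorded division events of the mother's age at
#' division; the model's counterpart of the experimentally reported
#' effective population doubling time.
#'
#' @param trajectory an `ib_trajectory`.
#' @return list with `mean_h`, `sd_h` and `n` divisions.
#' @export
division_cycle_stats <- function(trajectory) {
  cyc <- trajectory$events$cycle_h[trajectory$events$type == "division"]
  list(mean_h = mean(cyc), sd_h = stats::sd(cyc), n = length(cyc))
}

#' Effective population doubling time of a run
#'
#' Doubling time of the exponential (log-linear least squares) fit to the
#' total-count growth curve over the expansion window, the standard
#' population-level estimator that experimental doubling times refer to.
#' Complements [division_cycle_stats()], which averages individual
#' inter-division ages and therefore weights the fast early cycles.
#'
#' @param trajectory an `ib_trajectory`.
#' @param through_day fit window end (default day 8, the window over which
#'   experimental cross-section counts are reported).
#' @return doubling time in hours.
#' @export
effective_doubling_time <- function(trajectory, through_day = 8) {
  cnt <- trajectory$counts
  cnt <- cnt[cnt$day <= through_day & cnt$n_total >= 1, , drop = FALSE]
  if (nrow(cnt) < 2 || max(cnt$n_total) <= min(cnt$n_total))
    return(NA_real_)
  fit <- stats::lm(log2(n_total) ~ day, data = cnt)
  24 / unname(stats::coef(fit)[2])
}
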