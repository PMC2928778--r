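#' Classify boundary points as basal and cells as outer/inner
#'
#' A point is basal when it is a free sensor (growth or ECM kind) facing the
#' external medium: a probe cast `2 * d_contact` along its outward normal
#' must land in the exterior region of the domain (reachable from the box
#' edge), not inside another cell and not in the enclosed lumen. A cell is
#' outer when it owns at least one basal point. The exterior region is
#' found by rasterizing all cell polygons onto the fluid grid and
#' flood-filling from the box border.
#'
#' @param tissue an `ib_tissue`.
#' @param config an `ib_config` (for the probe distance and raster geometry).
#' @return list with `basal` (named list of logical vectors per cell id),
#'   `outer` (named logical per cell id), and the raster `labels` matrix
#'   (0 lumen, 1 tissue, 2 exterior).
#' @export
classify_points <- function(tissue, config) {
  n <- config$grid_n
  h <- config$domain_um / n
  mask <- matrix(0L, n, n)
  for (cell in tissue$cells)
    rasterize_polygon_cpp(mask, cell$xy[, 1], cell$xy[, 2], 0, 0, h)
  lab <- flood_exterior_cpp(mask)
  free_kinds <- c(receptor_kinds[["growth_sensor"]],
                  receptor_kinds[["ecm_receptor"]])
  probes <- lapply(tissue$cells, function(cell) {
    probe <- cell$xy + 2 * config$d_contact_um * outward_normals(cell$xy)
    ii <- pmin(pmax(round(probe[, 1] / h) + 1, 1), n)
    jj <- pmin(pmax(round(probe[, 2] / h) + 1, 1), n)
    lab[cbind(ii, jj)]
  })
  basal <- mapply(function(cell, pl) (cell$kind %in% free_kinds) & pl == 2L,
                  tissue$cells, probes, SIMPLIFY = FALSE)
  lumen_facing <- mapply(function(cell, pl) pl == 0L,
                         tissue$cells, probes, SIMPLIFY = FALSE)
  open <- lapply(probes, function(pl) pl != 1L)  # not inside another cell
  list(basal = basal, outer = vapply(basal, any, TRUE),
       lumen_facing = lumen_facing, open = open, labels = lab)
}

#' Assemble and disassemble cell-cell adhesion bonds
#'
#' Bonds stretched past `d_break` are disassembled (endpoints revert to
#' growth sensors). Free growth sensors on two distinct non-apoptotic cells
#' within `d_contact` then pair greedily by ascending distance and become
#' adhesion receptors joined by a short spring. Polarized cells do not form
#' new bonds with inner cells (their lumen-facing domain is apical), and
#' apoptotic cells form no new bonds.
#'
#' @param tissue an `ib_tissue`.
#' @param d_contact assembly distance, um.
#' @param d_break disassembly distance, um (`>= d_contact`).
#' @param bond_rest rest length of new bonds, um.
#' @param cls point classification from [classify_points()]; `NULL` for a
#'   tissue-only call (polarization exclusions then use stored flags only).
#' @return the updated tissue.
#' @export
update_adhesion <- function(tissue, d_contact, d_break, bond_rest = 0.4,
                            cls = NULL) {
  stopifnot(d_break >= d_contact)
  b <- tissue$bonds
  if (nrow(b)) {
    len <- bond_lengths(tissue)
    broken <- which(len > d_break)
    if (length(broken))
      tissue <- disassemble_bonds(tissue, broken, death_fate = FALSE)
  }
  elig <- function(cell) {
    if (identical(cell$phenotype, "apoptotic"))
      return(rep(FALSE, nrow(cell$xy)))
    cell$kind == receptor_kinds[["growth_sensor"]]
  }
  pairs <- neighbor_pairs(tissue, d_contact, eligible = elig)
  if (nrow(pairs) && !is.null(cls)) {
    # polarized outer cells never re-attach to inner cells
    pol <- vapply(tissue$cells, `[[`, TRUE, "polarized")
    keep <- logical(nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      a <- as.character(pairs$cell_a[r]); bb <- as.character(pairs$cell_b[r])
      bad <- (isTRUE(pol[[a]]) && !cls$outer[[bb]]) ||
             (isTRUE(pol[[bb]]) && !cls$outer[[a]])
      keep[r] <- !bad
    }
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (nrow(pairs)) {
    adh <- receptor_kinds[["adhesion_receptor"]]
    for (r in seq_len(nrow(pairs))) {
      ca <- get_cell(tissue, pairs$cell_a[r])
      cb <- get_cell(tissue, pairs$cell_b[r])
      ca$kind[pairs$idx_a[r]] <- adh
      cb$kind[pairs$idx_b[r]] <- adh
      tissue <- set_cell(set_cell(tissue, ca), cb)
    }
    tissue$bonds <- rbind(tissue$bonds, data.frame(
      cell_a = pairs$cell_a, idx_a = pairs$idx_a,
      cell_b = pairs$cell_b, idx_b = pairs$idx_b,
      rest = bond_rest))
  }
  tissue
}

bond_lengths <- function(tissue) {
  b <- tissue$bonds
  if (!nrow(b)) return(numeric())
  pa <- t(vapply(seq_len(nrow(b)), function(r)
    get_cell(tissue, b$cell_a[r])$xy[b$idx_a[r], ], numeric(2)))
  pb <- t(vapply(seq_len(nrow(b)), function(r)
    get_cell(tissue, b$cell_b[r])$xy[b$idx_b[r], ], numeric(2)))
  sqrt(rowSums((pa - pb)^2))
}

# Remove bond rows and assign the endpoint fates: a live inner cell losing a
# bond to a polarized or dying partner (`death_fate`) gains a death
# receptor; a polarized cell losing a bond to an inner or dying partner
# presents apical membrane to the nascent lumen (so the cleared space is
# never re-sensed as free); everything else reverts to a growth sensor.
disassemble_bonds <- function(tissue, rows, death_fate = FALSE, cls = NULL,
                              now = NULL) {
  if (!length(rows)) return(tissue)
  b <- tissue$bonds[rows, , drop = FALSE]
  for (r in seq_len(nrow(b))) {
    for (side in c("a", "b")) {
      id <- b[[paste0("cell_", side)]][r]
      pid <- b[[paste0("cell_", if (side == "a") "b" else "a")]][r]
      idx <- b[[paste0("idx_", side)]][r]
      cell <- get_cell(tissue, id)
      partner <- get_cell(tissue, pid)
      if (is.null(cell) || is.na(idx)) next
      is_inner <- !is.null(cls) && !isTRUE(cls$outer[[as.character(id)]])
      partner_gone <- is.null(partner) ||
        identical(partner$phenotype, "apoptotic")
      partner_inner <- !is.null(cls) && !is.null(partner) &&
        !isTRUE(cls$outer[[as.character(pid)]])
      ecm_engaged <- any(cell$kind == receptor_kinds[["ecm_receptor"]])
      # hysteresis: a cell that held basal contact within the last two
      # hours is a rim cell caught by raster flicker, not a detached
      # inner cell
      recently_outer <- !is.null(now) && !is.null(cell$last_outer) &&
        (now - cell$last_outer) < 2
      if (death_fate && is_inner && !recently_outer &&
          !identical(cell$phenotype, "apoptotic")) {
        cell$kind[idx] <- receptor_kinds[["death_receptor"]]
      } else if ((cell$polarized || (!is_inner && ecm_engaged)) &&
                 (partner_inner || partner_gone || death_fate)) {
        # outer cell with a matrix-committed basal domain: the freed
        # membrane faces the nascent lumen and becomes apical
        cell$kind[idx] <- receptor_kinds[["apical_marker"]]
        cell$polarized <- TRUE
      } else if (cell$kind[idx] == receptor_kinds[["adhesion_receptor"]]) {
        cell$kind[idx] <- receptor_kinds[["growth_sensor"]]
      }
      tissue <- set_cell(tissue, cell)
    }
  }
  tissue$bonds <- tissue$bonds[-rows, , drop = FALSE]
  tissue
}

#' Convert free sensors by local ECM density
#'
#' Free growth sensors whose local matrix concentration reaches the E
#' threshold become ECM receptors; ECM receptors whose concentration has
#' decayed below E revert (the rule is memoryless, so ECM-arrested cells may
#' re-enter growth if the matrix thins).
#'
#' @param tissue an `ib_tissue`.
#' @param E ECM density threshold (concentration units).
#' @return the updated tissue.
#' @export
update_ecm_receptors <- function(tissue, E) {
  gs <- receptor_kinds[["growth_sensor"]]
  er <- receptor_kinds[["ecm_receptor"]]
  for (id in names(tissue$cells)) {
    cell <- tissue$cells[[id]]
    up <- cell$kind == gs & cell$ecm >= E
    down <- cell$kind == er & cell$ecm < E
    if (any(up)) cell$kind[up] <- er
    if (any(down)) cell$kind[down] <- gs
    tissue <- set_cell(tissue, cell)
  }
  tissue
}

#' Epithelial polarization of outer cells
#'
#' An outer cell commits to polarity once it has developed all three
#' membrane domains: an ECM-engaged basal domain (at least one ECM
#' receptor; the basal side of a polarized epithelial cell is its
#' matrix-adhering side, which links the polarization clock to ECM
#' accumulation), lateral adhesion bonds to at least two other outer cells,
#' and contact with inner cells. After `apical_delay` hours its
#' inner-facing points (those bonded to inner cells) become apical markers
#' and the bonds to the inner cells are disassembled, queueing death
#' receptors on the detached inner-cell endpoints. Apical markers never
#' carry bonds.
#'
#' @param tissue an `ib_tissue`.
#' @param apical_delay hours between commitment and apical emergence.
#' @param cls classification from [classify_points()].
#' @param rule_dt hours advanced per call.
#' @return the updated tissue.
#' @export
update_polarization <- function(tissue, apical_delay, cls, rule_dt = 0,
                                now = NULL) {
  if (n_cells(tissue) < 2) return(tissue)
  b <- tissue$bonds
  for (id in names(tissue$cells)) {
    cell <- tissue$cells[[id]]
    if (identical(cell$phenotype, "apoptotic")) next
    if (!isTRUE(cls$outer[[id]])) { cell$apical_clock <- NA_real_
                                    tissue <- set_cell(tissue, cell); next }
    rows_a <- which(b$cell_a == cell$id)
    rows_b <- which(b$cell_b == cell$id)
    partners <- c(b$cell_b[rows_a], b$cell_a[rows_b])
    if (!length(partners)) next
    p_outer <- cls$outer[as.character(partners)]
    n_outer_partners <- length(unique(partners[p_outer]))
    has_inner <- any(!p_outer)
    has_basal_ecm <- cell$polarized ||
      any(cell$kind == receptor_kinds[["ecm_receptor"]])
    gs <- receptor_kinds[["growth_sensor"]]
    lum_free <- cls$lumen_facing[[id]] & cell$kind == gs
    if (n_outer_partners >= 2 && has_basal_ecm &&
        (has_inner || any(lum_free))) {
      cell$apical_clock <- if (is.na(cell$apical_clock)) rule_dt
                           else cell$apical_clock + rule_dt
    } else if (!cell$polarized) {
      cell$apical_clock <- NA_real_
    }
    if (!is.na(cell$apical_clock) && cell$apical_clock >= apical_delay &&
        (has_inner || any(lum_free))) {
      ap <- receptor_kinds[["apical_marker"]]
      inner_rows <- c(rows_a[!cls$outer[as.character(b$cell_b[rows_a])]],
                      rows_b[!cls$outer[as.character(b$cell_a[rows_b])]])
      own_idx <- c(b$idx_a[intersect(inner_rows, rows_a)],
                   b$idx_b[intersect(inner_rows, rows_b)])
      cell$kind[own_idx] <- ap
      cell$kind[lum_free] <- ap
      cell$polarized <- TRUE
      tissue <- set_cell(tissue, cell)
      if (length(inner_rows)) {
        tissue <- disassemble_bonds(tissue, inner_rows, death_fate = TRUE,
                                    cls = cls, now = now)
        b <- tissue$bonds
      }
      next
    }
    tissue <- set_cell(tissue, cell)
  }
  # close the apical domain: free sensors of a polarized cell flanked by an
  # apical marker and facing the lumen side become apical too
  for (id in names(tissue$cells)) {
    cell <- tissue$cells[[id]]
    if (!cell$polarized) next
    ap <- receptor_kinds[["apical_marker"]]
    gs <- receptor_kinds[["growth_sensor"]]
    n <- length(cell$kind)
    ipn <- c(2:n, 1); imn <- c(n, 1:(n - 1))
    grow <- which(cell$kind == gs & !cls$basal[[id]] &
                  (cell$kind[ipn] == ap | cell$kind[imn] == ap))
    if (length(grow)) { cell$kind[grow] <- ap; tissue <- set_cell(tissue, cell) }
  }
  tissue
}

#' Materialize death receptors on detached inner cells
#'
#' Death receptors appear on inner cells at points that lost an adhesion
#' bond to a polarized outer cell or to a dying cell (converted inside the
#' disassembly bookkeeping), and over the whole free membrane of an inner
#' cell that is fully detached - including daughters deposited into the
#' lumen, which the polarized shell refuses to re-bind. Outer (or recently
#' outer) cells shed any death receptors they carry.
#'
#' @param tissue an `ib_tissue`.
#' @param cls classification from [classify_points()].
#' @param now simulation time in hours (for the outer-status hysteresis).
#' @return the updated tissue.
#' @export
update_death_receptors <- function(tissue, cls, now = NULL) {
  dr <- receptor_kinds[["death_receptor"]]
  gs <- receptor_kinds[["growth_sensor"]]
  for (id in names(tissue$cells)) {
    cell <- tissue$cells[[id]]
    protected <- isTRUE(cls$outer[[id]]) ||
      any(cell$kind == receptor_kinds[["ecm_receptor"]])
    if (protected && !identical(cell$phenotype, "apoptotic") &&
        any(cell$kind == dr)) {
      # a formerly inner cell pushed to the rim regains sensing capacity
      cell$kind[cell$kind == dr] <- gs
      tissue <- set_cell(tissue, cell)
      next
    }
    if (identical(cell$phenotype, "apoptotic") || isTRUE(cls$outer[[id]]))
      next
    rows <- tissue$bonds$cell_a == cell$id | tissue$bonds$cell_b == cell$id
    partners <- c(tissue$bonds$cell_b[tissue$bonds$cell_a == cell$id],
                  tissue$bonds$cell_a[tissue$bonds$cell_b == cell$id])
    outer_partner <- length(partners) &&
      any(vapply(as.character(partners), function(p)
        isTRUE(cls$outer[[p]]), TRUE))
    recently_outer <- !is.null(now) && !is.null(cell$last_outer) &&
      (now - cell$last_outer) < 2
    detached_from_shell <- !any(rows) ||
      (!outer_partner && any(cls$lumen_facing[[id]]))
    if (detached_from_shell && !recently_outer && cell$age > 2) {
      free <- cell$kind == gs
      if (any(free)) {
        cell$kind[free] <- dr
        tissue <- set_cell(tissue, cell)
      }
    }
  }
  tissue
}

# Free-space mask. For the growth decision, lumen sensing lets apical
# markers count as free and releasing contact inhibition additionally lets
# adhesion receptors count. Fluid sources are only ever placed at membrane
# stretches that really face open space (growth sensors, plus apical
# markers under lumen sensing): adhered membrane cannot transport fluid, so
# crowding still slows growth even when the growth *decision* ignores it.
free_point_mask <- function(cell, flags, for_sources = FALSE) {
  free <- cell$kind == receptor_kinds[["growth_sensor"]]
  if (isTRUE(flags$lumen_sensing))
    free <- free | cell$kind == receptor_kinds[["apical_marker"]]
  if (!for_sources && isTRUE(flags$contact_inhibition_released))
    free <- free | cell$kind == receptor_kinds[["adhesion_receptor"]]
  free
}

#' Growth decision for a matured cell
#'
#' A cell grows only if it senses enough free space: its free-sensor
#' fraction must reach `G` percent. With `lumen_sensing` apical markers count
#' as free (luminal space promotes growth); with
#' `contact_inhibition_released` adhesion receptors count as free as well.
#' Cells below threshold are in contact inhibition.
#'
#' @param cell an `ib_cell` with `maturation == 0`, not apoptotic.
#' @param G growth threshold, percent of membrane sensors.
#' @param flags list with `lumen_sensing` and `contact_inhibition_released`.
#' @return `"growing"` or `"contact_inhibited"`.
#' @export
decide_growth <- function(cell, G,
                          flags = list(lumen_sensing = FALSE,
                                       contact_inhibition_released = FALSE)) {
  stopifnot(!identical(cell$phenotype, "apoptotic"), cell$maturation <= 0)
  if (mean(free_point_mask(cell, flags)) >= G / 100) "growing"
  else "contact_inhibited"
}

#' Balanced growth sources and sinks for a growing cell
#'
#' Fluid transport through the membrane is modeled by placing a point
#' source just inside the membrane at every free sensor, so a fully free
#' cell gains area at `source_strength` um^2/h and a partially adhered cell
#' proportionally to its free-sensor fraction. The balancing sinks are
#' placed just outside the membrane, but only at points that face open
#' space (exterior medium or lumen): a sink lowered into an abutting
#' neighbour would drain it. Strengths always sum to zero per cell; a
#' fully enclosed cell cannot grow.
#'
#' @param cell an `ib_cell`.
#' @param source_strength area gain rate of a fully free cell, um^2/h.
#' @param offset distance of sources/sinks from the membrane, um.
#' @param flags rule switches as in [decide_growth()].
#' @param open logical mask of points whose outward side faces open space
#'   (exterior medium or lumen, not a packed neighbour); sinks are only
#'   placed there, so a source/sink pair never drains an abutting cell.
#' @return list with `positions` (m x 2) and `strength` (length m), empty
#'   for non-growing cells.
#' @export
place_growth_sources <- function(cell, source_strength, offset,
                                 flags = list(lumen_sensing = FALSE,
                                              contact_inhibition_released = FALSE),
                                 open = rep(TRUE, nrow(cell$xy))) {
  none <- list(positions = matrix(numeric(), 0, 2), strength = numeric())
  if (!identical(cell$phenotype, "growing")) return(none)
  n_free <- sum(free_point_mask(cell, flags, for_sources = TRUE))
  port <- which(open)   # membrane stretches facing exterior medium or lumen
  if (!n_free || !length(port)) return(none)
  nrm <- outward_normals(cell$xy)[port, , drop = FALSE]
  q_total <- source_strength * n_free / nrow(cell$xy)
  q <- q_total / length(port)
  inside <- cell$xy[port, , drop = FALSE] - offset * nrm
  outside <- cell$xy[port, , drop = FALSE] + offset * nrm
  list(positions = rbind(inside, outside),
       strength = c(rep(q, length(port)), rep(-q, length(port))))
}

# sinks inside / sources outside: drains an apoptotic cell at `rate` um^2/h
apoptotic_sources <- function(cell, rate, offset) {
  nrm <- outward_normals(cell$xy)
  q <- rate / nrow(cell$xy)
  list(positions = rbind(cell$xy - offset * nrm, cell$xy + offset * nrm),
       strength = c(rep(-q, nrow(cell$xy)), rep(q, nrow(cell$xy))))
}

#' Division trigger and contractile-ring assignment
#'
#' A growing cell whose area has doubled becomes dividing and receives its
#' contractile ring. While the tissue is smaller than
#' `division_mode_switch` cells, outer cells divide symmetrically: the
#' cleavage chord runs orthogonal to the basal domain, from the basal-arc
#' midpoint to the antipodal point, so both daughters keep basal contact.
#' In later stages division is asymmetric: the chord runs parallel to the
#' basal domain (between the two lateral mid-sides), producing one basal and
#' one luminal daughter. Cells without a basal domain use the
#' lowest-index diameter.
#'
#' @param cell an `ib_cell`.
#' @param n_tissue_cells current tissue size.
#' @param division_mode_switch tissue size at which orientation switches.
#' @param basal logical vector marking the cell's basal points.
#' @return the cell, with `phenotype = "dividing"` and `ring` set if the
#'   area criterion is met; unchanged otherwise.
#' @export
check_division <- function(cell, n_tissue_cells, division_mode_switch,
                           basal = rep(FALSE, nrow(cell$xy))) {
  if (!identical(cell$phenotype, "growing")) return(cell)
  if (polygon_area(cell) < 2 * cell$rest_area) return(cell)
  n <- nrow(cell$xy)
  half <- as.integer(round(n / 2))
  if (!any(basal)) {
    ring <- c(1L, 1L + half)
  } else {
    arc <- longest_true_arc(basal)
    mid <- arc$mid
    if (n_tissue_cells < division_mode_switch) {
      ring <- c(mid, wrap_index(mid + half, n))        # orthogonal to basal
    } else {
      # chord parallel to basal: midpoints of the two lateral sides
      a <- wrap_index(arc$end + round(wrap_len(arc$end,
             wrap_index(mid + half, n), n) / 2), n)
      b <- wrap_index(wrap_index(mid + half, n) + round(wrap_len(
             wrap_index(mid + half, n), arc$start, n) / 2), n)
      ring <- c(min(a, b), max(a, b))
      if (ring[1] == ring[2]) ring <- c(mid, wrap_index(mid + half, n))
    }
  }
  ring <- sort(wrap_index(ring, n))
  if (ring[1] == ring[2]) ring <- c(1L, 1L + half)
  sep <- wrap_len(ring[1], ring[2], n)
  if (min(sep, n - sep) < n / 4)       # guard against sliver daughters
    ring <- sort(c(ring[1], wrap_index(ring[1] + half, n)))
  cell$phenotype <- "dividing"
  cell$ring <- as.integer(ring)
  cell$rest_ring <- sqrt(sum((cell$xy[ring[2], ] - cell$xy[ring[1], ])^2))
  cell$division_clock <- 0
  cell
}

wrap_index <- function(i, n) ((i - 1L) %% n) + 1L

# steps from i forward to j on a ring of n points
wrap_len <- function(i, j, n) (j - i) %% n

# longest circular run of TRUE; returns start, end and middle indices
longest_true_arc <- function(x) {
  n <- length(x)
  if (all(x)) return(list(start = 1L, end = n, mid = 1L))
  r <- rle(c(x, x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values & starts <= n)
  best <- cand[which.max(pmin(r$lengths[cand], n))]
  s <- starts[best]
  len <- min(r$lengths[best], n)
  list(start = wrap_index(s, n), end = wrap_index(s + len - 1, n),
       mid = wrap_index(s + (len - 1) %/% 2, n))
}

#' Split a pinched dividing cell into two daughters
#'
#' Partitions the polygon along the chord between the contracted ring
#' endpoints. Both daughters are simple polygons with all points reset to
#' growth sensors (bonds re-form at the next adhesion update), fresh
#' maturation clocks, and ids `max id + 1, + 2`.
#'
#' @param cell a dividing `ib_cell` whose ring has contracted.
#' @param next_id first of the two new ids.
#' @param now simulation time (hours), recorded as the daughters' birth.
#' @param maturation maturation period for the daughters, hours.
#' @param spacing boundary spacing used to resample the daughters.
#' @return list of two `ib_cell` daughters (largest share of the mother's
#'   basal side first by construction of the ring).
#' @export
split_cell <- function(cell, next_id, now = 0, maturation = 4, spacing = 0.7) {
  stopifnot(!is.null(cell$ring))
  i <- cell$ring[1]; j <- cell$ring[2]
  n <- nrow(cell$xy)
  idx_a <- i:j
  idx_b <- c(j:n, 1:i)
  daughters <- list()
  for (k in 1:2) {
    idx <- if (k == 1) idx_a else idx_b
    if (length(idx) < 3) stop(ibcell_condition("ibcell_geometry_defect",
                                               "degenerate division chord"))
    xy <- cell$xy[idx, , drop = FALSE]
    ecm <- cell$ecm[idx]
    if (shoelace(xy) < 0) { xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
                            ecm <- rev(ecm) }
    if (polygon_self_intersects_cpp(xy[, 1], xy[, 2])) {
      # the pinched neck can fold through the chord; drop the folded loop
      keep <- untangle_indices(xy, min_points = 6L)
      if (is.null(keep))
        stop(ibcell_condition("ibcell_geometry_defect",
                              "division produced a self-intersecting polygon"))
      xy <- xy[keep, , drop = FALSE]
      ecm <- ecm[keep]
    }
    d <- new_cell(next_id + k - 1L, polygon_centroid(xy),
                  n_points = nrow(xy), rest_area = cell$rest_area,
                  birth_time = now, maturation = maturation)
    d$xy <- xy
    d$kind <- rep(receptor_kinds[["growth_sensor"]], nrow(xy))
    d$ecm <- ecm
    d <- resample_boundary(d, spacing)$cell
    daughters[[k]] <- d
  }
  daughters
}

#' Apoptosis triggering, shrinkage bookkeeping and removal
#'
#' A cell whose death-receptor fraction reaches `D` percent becomes
#' apoptotic after `death_delay` hours; the engine then drains it with
#' balanced sinks/sources. Its remaining bonds are shed `detach_delay` hours
#' after death starts (detached endpoints on inner neighbours become death
#' receptors, propagating the cue), and the cell is removed and logged when
#' its area falls below 10 percent of its rest area.
#'
#' @param tissue an `ib_tissue`.
#' @param D death threshold, percent.
#' @param death_delay,detach_delay hours.
#' @param cls classification from [classify_points()].
#' @param rule_dt hours advanced per call.
#' @param now simulation time (hours) for the removal log.
#' @return the updated tissue.
#' @export
update_apoptosis <- function(tissue, D, death_delay = 4, detach_delay = 4,
                             cls = NULL, rule_dt = 0, now = 0) {
  dr <- receptor_kinds[["death_receptor"]]
  for (id in names(tissue$cells)) {
    cell <- tissue$cells[[id]]
    if (identical(cell$phenotype, "apoptotic")) next
    frac <- mean(cell$kind == dr)
    if (frac >= D / 100 && D <= 100) {
      cell$death_clock <- if (is.na(cell$death_clock)) rule_dt
                          else cell$death_clock + rule_dt
      if (cell$death_clock >= death_delay) {
        cell$phenotype <- "apoptotic"
        cell$ring <- NULL
        cell$rest_ring <- NA_real_
        cell$detach_clock <- 0
      }
    } else {
      cell$death_clock <- NA_real_
    }
    tissue <- set_cell(tissue, cell)
  }
  # shed bonds of dying cells after the detachment delay
  b <- tissue$bonds
  if (nrow(b)) {
    shed <- integer()
    for (id in names(tissue$cells)) {
      cell <- tissue$cells[[id]]
      if (!identical(cell$phenotype, "apoptotic")) next
      cell$detach_clock <- cell$detach_clock + rule_dt
      tissue <- set_cell(tissue, cell)
      if (cell$detach_clock >= detach_delay)
        shed <- c(shed, which(b$cell_a == cell$id | b$cell_b == cell$id))
    }
    tissue <- disassemble_bonds(tissue, unique(shed), death_fate = TRUE,
                                cls = cls)
  }
  # removal at the area floor
  for (id in names(tissue$cells)) {
    cell <- tissue$cells[[id]]
    if (!identical(cell$phenotype, "apoptotic")) next
    area <- polygon_area(cell)
    if (area < 0.1 * cell$rest_area) {
      rows <- which(tissue$bonds$cell_a == cell$id |
                    tissue$bonds$cell_b == cell$id)
      tissue <- disassemble_bonds(tissue, rows, death_fate = TRUE, cls = cls,
                                  now = now)
      tissue$removed_log <- rbind(tissue$removed_log,
                                  data.frame(time = now, cell_id = cell$id,
                                             area = area))
      tissue$cells[[id]] <- NULL
    }
  }
  tissue
}

#' ECM secretion and decay along cell boundaries
#'
#' Per boundary point, matrix concentration obeys
#' `ecm' = secretion * [basal] - decay * ecm` (forward Euler): constant
#' secretion along basal domains and first-order decay everywhere, giving a
#' basal steady state of `secretion / decay`.
#'
#' @param tissue an `ib_tissue`.
#' @param secretion concentration per hour at basal points.
#' @param decay 1/hour.
#' @param dt hours.
#' @param basal named list of logical vectors (from [classify_points()]).
#' @return the updated tissue.
#' @export
update_ecm_field <- function(tissue, secretion, decay, dt, basal) {
  for (id in names(tissue$cells)) {
    cell <- tissue$cells[[id]]
    src <- secretion * as.numeric(basal[[id]])
    cell$ecm <- pmax(0, cell$ecm + dt * (src - decay * cell$ecm))
    tissue <- set_cell(tissue, cell)
  }
  tissue
}
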