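#' Membrane receptor kinds
#'
#' Every boundary point of a cell carries exactly one receptor/sensor label.
#' Growth sensors are the default state; the other kinds are recruited by the
#' life-process rules: adhesion receptors when two cells bond, ECM receptors
#' when local matrix density exceeds the E threshold, apical markers when an
#' outer cell polarizes, and death receptors when an inner cell is detached
#' from a polarized or dying neighbour.
#'
#' @format named integer vector mapping kind name to its integer code.
#' @export
receptor_kinds <- c(
  growth_sensor = 1L, adhesion_receptor = 2L, ecm_receptor = 3L,
  apical_marker = 4L, death_receptor = 5L
)

kind_code <- function(kind) {
  if (is.character(kind)) {
    code <- receptor_kinds[kind]
    if (any(is.na(code))) stop("unknown receptor kind: ", kind)
    unname(code)
  } else as.integer(kind)
}

#' Create a circular cell
#'
#' Cells are closed counterclockwise polygons of labelled boundary points.
#' New (daughter-sized) cells are circles of the typical epithelial
#' cross-section, about 20 um across (area ~314 um^2); a cell divides once
#' its area has doubled.
#'
#' @param id integer cell id (unique within a tissue, never reused).
#' @param center length-2 numeric, um.
#' @param area initial polygon area, um^2; also the rest area unless given.
#' @param n_points boundary points on the initial circle.
#' @param rest_area area at which the cell is "grown" is `2 * rest_area`.
#' @param birth_time simulation time of birth (hours).
#' @param maturation hours of post-division rest before growth eligibility.
#' @return an object of class `ib_cell`.
#' @export
new_cell <- function(id, center, area = pi * 10^2,
                     n_points = 64L, rest_area = area, birth_time = 0,
                     maturation = 0) {
  # regular n-gon inscribed radius chosen so the polygon area equals `area`
  r <- sqrt(2 * area / (n_points * sin(2 * pi / n_points)))
  th <- 2 * pi * (seq_len(n_points) - 1) / n_points
  xy <- cbind(center[1] + r * cos(th), center[2] + r * sin(th))
  cell <- list(
    id = as.integer(id), xy = xy,
    kind = rep(receptor_kinds[["growth_sensor"]], n_points),
    ecm = rep(0, n_points),
    phenotype = "resting", polarized = FALSE,
    rest_area = rest_area, birth_time = birth_time,
    maturation = maturation, age = 0,
    ring = NULL, rest_ring = NA_real_,
    death_clock = NA_real_, apical_clock = NA_real_, detach_clock = NA_real_
  )
  class(cell) <- "ib_cell"
  cell
}

#' @export
print.ib_cell <- function(x, ...) {
  cat(sprintf("<ib_cell #%d> %s%s, %d points, area %.1f um^2\n",
              x$id, x$phenotype, if (x$polarized) " (polarized)" else "",
              nrow(x$xy), polygon_area(x)))
  invisible(x)
}

#' Polygon area (shoelace)
#'
#' @param x an `ib_cell` or an m x 2 coordinate matrix.
#' @param check signal a geometry defect for self-intersecting polygons.
#' @return positive area in um^2 regardless of orientation.
#' @export
polygon_area <- function(x, check = FALSE) {
  xy <- if (inherits(x, "ib_cell")) x$xy else as.matrix(x)
  if (check && polygon_self_intersects_cpp(xy[, 1], xy[, 2]))
    stop(ibcell_condition("ibcell_geometry_defect",
                          "self-intersecting polygon"))
  abs(shoelace(xy))
}

shoelace <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(xy))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# enforce counterclockwise orientation (positive shoelace)
ensure_ccw <- function(xy) {
  if (shoelace(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

#' Outward unit normals of a counterclockwise polygon
#'
#' Central-difference tangents rotated by -90 degrees.
#'
#' @param xy m x 2 coordinate matrix, counterclockwise.
#' @return m x 2 matrix of unit normals.
#' @export
outward_normals <- function(xy) {
  m <- nrow(xy)
  ip <- c(2:m, 1); im <- c(m, 1:(m - 1))
  tx <- xy[ip, 1] - xy[im, 1]
  ty <- xy[ip, 2] - xy[im, 2]
  len <- sqrt(tx^2 + ty^2)
  len[len == 0] <- 1
  cbind(ty / len, -tx / len)
}

#' Fraction of boundary points of a given receptor kind
#'
#' Phenotype decisions are gated on these fractions: a cell grows when its
#' free growth-sensor fraction reaches the G threshold and starts apoptosis
#' when its death-receptor fraction reaches the D threshold. Fractions are
#' measured over point counts (points are kept near-uniformly spaced, so this
#' agrees with an arc-length measure to first order).
#'
#' @param cell an `ib_cell`.
#' @param kind a kind name from [receptor_kinds] (or its integer code).
#' @return fraction in `[0, 1]`.
#' @export
receptor_fraction <- function(cell, kind) {
  if (nrow(cell$xy) < 3) stop("cell has fewer than 3 boundary points")
  mean(cell$kind == kind_code(kind))
}

#' Restore boundary point spacing
#'
#' Growing membranes stretch their edges; this keeps every edge length within
#' `[0.5, 1.5] * spacing` by inserting chord midpoints on over-stretched
#' edges (area-neutral) and dropping points from over-dense runs. Inserted
#' points take the shared kind of the edge endpoints (growth sensor on a
#' tie) and the mean of their ECM load. Protected points (bonded or ring
#' endpoints) are never dropped.
#'
#' @param cell an `ib_cell`.
#' @param spacing target spacing, um.
#' @param protect integer indices that must survive.
#' @return list with the updated `cell` and `map`, an integer vector giving
#'   the new index of every old point.
#' @export
resample_boundary <- function(cell, spacing, protect = integer()) {
  map <- seq_len(nrow(cell$xy))
  for (pass in 1:6) {
    n <- nrow(cell$xy)
    xy <- cell$xy
    ip <- c(2:n, 1)
    elen <- sqrt(rowSums((xy[ip, , drop = FALSE] - xy)^2))
    long <- which(elen > 1.5 * spacing)
    short <- which(elen < 0.5 * spacing)
    if (!length(long) && !length(short)) break
    if (length(long)) {
      cell <- insert_midpoints(cell, long)
      # indices after `long[i]` shift up by i
      shift <- vapply(map, function(old) sum(long < old), integer(1))
      map <- map + shift
      protect <- protect + vapply(protect, function(old) sum(long < old),
                                  integer(1))
      next
    }
    # drop at most one point per pass from the densest run
    cand <- setdiff(short, protect)
    cand <- setdiff(cand, 0L)
    # never let neighbouring protected structure collapse; keep n >= 8
    if (!length(cand) || n <= 8) break
    drop <- cand[which.min(elen[cand])]
    keep <- setdiff(seq_len(n), drop)
    cell$xy <- cell$xy[keep, , drop = FALSE]
    cell$kind <- cell$kind[keep]
    cell$ecm <- cell$ecm[keep]
    map[map == drop] <- NA_integer_
    map <- map - ifelse(!is.na(map) & map > drop, 1L, 0L)
    protect <- protect - ifelse(protect > drop, 1L, 0L)
    if (!is.null(cell$ring)) {
      cell$ring <- cell$ring - ifelse(cell$ring > drop, 1L, 0L)
    }
  }
  list(cell = cell, map = map)
}

insert_midpoints <- function(cell, edges) {
  n <- nrow(cell$xy)
  ip <- c(2:n, 1)
  pieces_xy <- vector("list", n)
  pieces_kind <- vector("list", n)
  pieces_ecm <- vector("list", n)
  gs <- receptor_kinds[["growth_sensor"]]
  for (i in seq_len(n)) {
    pieces_xy[[i]] <- cell$xy[i, , drop = FALSE]
    pieces_kind[[i]] <- cell$kind[i]
    pieces_ecm[[i]] <- cell$ecm[i]
    if (i %in% edges) {
      j <- ip[i]
      mid <- (cell$xy[i, ] + cell$xy[j, ]) / 2
      k <- if (cell$kind[i] == cell$kind[j]) cell$kind[i] else gs
      pieces_xy[[i]] <- rbind(pieces_xy[[i]], mid)
      pieces_kind[[i]] <- c(pieces_kind[[i]], k)
      pieces_ecm[[i]] <- c(pieces_ecm[[i]], (cell$ecm[i] + cell$ecm[j]) / 2)
    }
  }
  new_xy <- do.call(rbind, pieces_xy)
  cell$kind <- unlist(pieces_kind, use.names = FALSE)
  cell$ecm <- unlist(pieces_ecm, use.names = FALSE)
  if (!is.null(cell$ring)) {
    cell$ring <- cell$ring +
      vapply(cell$ring, function(old) sum(edges < old), integer(1))
  }
  cell$xy <- new_xy
  cell
}

# Remove the smaller loop at each proper self-crossing of a closed chain.
# Returns the kept (original) point indices, or NULL if untangling failed.
untangle_indices <- function(xy, min_points = 8L) {
  keep <- seq_len(nrow(xy))
  for (pass in 1:8) {
    cross <- first_self_intersection_cpp(xy[keep, 1], xy[keep, 2])
    if (!length(cross)) return(keep)
    i <- cross[1]; j <- cross[2]
    loop <- (i + 1):j                 # local indices of one loop
    other_loop <- setdiff(seq_along(keep), loop)
    cands <- if (length(loop) <= length(other_loop))
      list(loop, other_loop) else list(other_loop, loop)
    drop_local <- NULL
    for (cand in cands)
      if (length(keep) - length(cand) >= min_points) { drop_local <- cand
                                                       break }
    if (is.null(drop_local)) return(NULL)
    keep <- keep[-drop_local]
  }
  cross <- first_self_intersection_cpp(xy[keep, 1], xy[keep, 2])
  if (length(cross)) NULL else keep
}

# untangle a cell's polygon in place; returns NULL if impossible
untangle_cell <- function(cell, min_points = 8L) {
  keep <- untangle_indices(cell$xy, min_points)
  if (is.null(keep)) return(NULL)
  if (length(keep) < nrow(cell$xy)) {
    cell$xy <- cell$xy[keep, , drop = FALSE]
    cell$kind <- cell$kind[keep]
    cell$ecm <- cell$ecm[keep]
  }
  attr(cell, "kept") <- keep
  cell
}

#' Create an empty tissue
#'
#' The tissue holds the cell collection, the cell-cell adhesion bonds and a
#' log of removed (apoptosed) cells. Cell ids are never reused.
#'
#' @param cells optional list of `ib_cell` objects.
#' @return an object of class `ib_tissue`.
#' @export
tissue <- function(cells = list()) {
  t <- list(
    cells = stats::setNames(cells, vapply(cells, function(c) as.character(c$id),
                                          character(1))),
    bonds = empty_bonds(),
    next_id = if (length(cells)) max(vapply(cells, `[[`, 0L, "id")) + 1L else 1L,
    removed_log = data.frame(time = numeric(), cell_id = integer(),
                             area = numeric())
  )
  class(t) <- "ib_tissue"
  t
}

empty_bonds <- function() {
  data.frame(cell_a = integer(), idx_a = integer(),
             cell_b = integer(), idx_b = integer(),
             rest = numeric())
}

#' @export
print.ib_tissue <- function(x, ...) {
  ph <- table(vapply(x$cells, `[[`, "", "phenotype"))
  cat(sprintf("<ib_tissue> %d cells, %d bonds, %d removed\n",
              length(x$cells), nrow(x$bonds), nrow(x$removed_log)))
  if (length(ph)) cat("  ", paste(names(ph), ph, sep = ": ", collapse = ", "),
                      "\n")
  invisible(x)
}

n_cells <- function(tis) length(tis$cells)

live_ids <- function(tis) vapply(tis$cells, `[[`, 0L, "id")

get_cell <- function(tis, id) tis$cells[[as.character(id)]]

set_cell <- function(tis, cell) {
  tis$cells[[as.character(cell$id)]] <- cell
  tis
}

#' Candidate adhesion point pairs
#'
#' Finds inter-cell pairs of the given points within `d_contact`, matched
#' greedily by ascending distance with ties broken by (cell id, point index);
#' each point appears in at most one pair, so the result is deterministic
#' under any input reordering.
#'
#' @param tissue an `ib_tissue`.
#' @param d_contact pairing distance, um.
#' @param eligible optional function `(cell) -> logical vector` selecting
#'   points that may pair (default: free growth sensors).
#' @return data frame with columns cell_a, idx_a, cell_b, idx_b, dist.
#' @export
neighbor_pairs <- function(tissue, d_contact,
                           eligible = function(cell)
                             cell$kind == receptor_kinds[["growth_sensor"]]) {
  stopifnot(d_contact > 0)
  cells <- tissue$cells[order(vapply(tissue$cells, `[[`, 0L, "id"))]
  pts <- lapply(cells, function(c) {
    sel <- which(eligible(c))
    if (!length(sel)) return(NULL)
    cbind(id = c$id, idx = sel, x = c$xy[sel, 1], y = c$xy[sel, 2])
  })
  pts <- pts[!vapply(pts, is.null, TRUE)]
  if (length(pts) < 2) return(cbind(empty_bonds()[0, 1:4], dist = numeric()))
  out <- list()
  for (i in seq_len(length(pts) - 1)) {
    for (j in (i + 1):length(pts)) {
      A <- pts[[i]]; B <- pts[[j]]
      if (min(A[, "x"]) > max(B[, "x"]) + d_contact ||
          min(B[, "x"]) > max(A[, "x"]) + d_contact ||
          min(A[, "y"]) > max(B[, "y"]) + d_contact ||
          min(B[, "y"]) > max(A[, "y"]) + d_contact) next
      dx <- outer(A[, "x"], B[, "x"], "-")
      dy <- outer(A[, "y"], B[, "y"], "-")
      d <- sqrt(dx^2 + dy^2)
      hit <- which(d <= d_contact, arr.ind = TRUE)
      if (nrow(hit)) {
        out[[length(out) + 1]] <- data.frame(
          cell_a = A[hit[, 1], "id"], idx_a = A[hit[, 1], "idx"],
          cell_b = B[hit[, 2], "id"], idx_b = B[hit[, 2], "idx"],
          dist = d[hit])
      }
    }
  }
  if (!length(out)) return(cbind(empty_bonds()[0, 1:4], dist = numeric()))
  cand <- do.call(rbind, out)
  cand <- cand[order(cand$dist, cand$cell_a, cand$idx_a,
                     cand$cell_b, cand$idx_b), , drop = FALSE]
  used <- character()
  take <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    ka <- paste(cand$cell_a[r], cand$idx_a[r])
    kb <- paste(cand$cell_b[r], cand$idx_b[r])
    if (!(ka %in% used) && !(kb %in% used)) {
      take[r] <- TRUE
      used <- c(used, ka, kb)
    }
  }
  rownames(cand) <- NULL
  cand[take, , drop = FALSE]
}
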