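#' Elastic membrane forces
#'
#' The plasma membrane is a closed chain of linear (Hookean) springs between
#' consecutive boundary points: each edge of length `|d|` pulls its endpoints
#' together (or pushes apart) with magnitude `k * (|d| - rest_length)` along
#' the edge. Forces sum to zero over the cell (Newton's third law).
#'
#' @param cell an `ib_cell`.
#' @param stiffness spring constant, force per um.
#' @param rest_length edge rest length, um.
#' @return n x 2 matrix of per-point forces.
#' @export
membrane_forces <- function(cell, stiffness, rest_length) {
  stopifnot(stiffness > 0, rest_length > 0)
  xy <- cell$xy
  n <- nrow(xy)
  ip <- c(2:n, 1)
  d <- xy[ip, , drop = FALSE] - xy
  len <- sqrt(rowSums(d^2))
  if (any(len == 0))
    stop(ibcell_condition("ibcell_geometry_defect",
                          "coincident adjacent boundary points"))
  fmag <- stiffness * (len - rest_length) / len
  fe <- d * fmag                       # force on edge start, toward end
  fe - fe[c(n, 1:(n - 1)), , drop = FALSE]
}

#' Cell-cell adhesion forces
#'
#' Each adhesion bond is a short linear spring between adhesion receptors on
#' two distinct cells. Returns equal and opposite endpoint forces, keyed by
#' cell id.
#'
#' @param tissue an `ib_tissue` whose `bonds` table is current.
#' @param stiffness spring constant, force per um.
#' @return named list (by cell id) of n x 2 force matrices, covering only
#'   cells that carry bonds.
#' @export
adhesion_forces <- function(tissue, stiffness) {
  out <- list()
  b <- tissue$bonds
  if (!nrow(b)) return(out)
  for (r in seq_len(nrow(b))) {
    ca <- get_cell(tissue, b$cell_a[r])
    cb <- get_cell(tissue, b$cell_b[r])
    pa <- ca$xy[b$idx_a[r], ]
    pb <- cb$xy[b$idx_b[r], ]
    d <- pb - pa
    len <- sqrt(sum(d^2))
    f <- if (len > 0) stiffness * (len - b$rest[r]) * d / len else c(0, 0)
    ka <- as.character(b$cell_a[r]); kb <- as.character(b$cell_b[r])
    if (is.null(out[[ka]])) out[[ka]] <- matrix(0, nrow(ca$xy), 2)
    if (is.null(out[[kb]])) out[[kb]] <- matrix(0, nrow(cb$xy), 2)
    out[[ka]][b$idx_a[r], ] <- out[[ka]][b$idx_a[r], ] + f
    out[[kb]][b$idx_b[r], ] <- out[[kb]][b$idx_b[r], ] - f
  }
  out
}

#' Contractile-ring forces of a dividing cell
#'
#' Division is driven by a stiff spring between two opposite boundary points
#' (the ring endpoints) whose rest length shrinks toward zero, pinching the
#' membrane until the cell is split geometrically.
#'
#' @param cell an `ib_cell`; non-dividing cells yield zero forces.
#' @param stiffness ring spring constant.
#' @return n x 2 matrix of per-point forces.
#' @export
contractile_forces <- function(cell, stiffness) {
  f <- matrix(0, nrow(cell$xy), 2)
  if (!identical(cell$phenotype, "dividing") || is.null(cell$ring)) return(f)
  i <- cell$ring[1]; j <- cell$ring[2]
  if (i == j)
    stop(ibcell_condition("ibcell_invalid_ring",
                          "ring endpoints coincide in index"))
  d <- cell$xy[j, ] - cell$xy[i, ]
  len <- sqrt(sum(d^2))
  if (len == 0) return(f)
  fv <- stiffness * (len - cell$rest_ring) * d / len
  f[i, ] <- fv
  f[j, ] <- -fv
  f
}
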