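# Small geometric fixtures shared across the suite; all built in code.

# regular polygon cell, area-exact construction as in new_cell()
circle_cell <- function(id = 1L, center = c(20, 20), area = pi * 10^2,
                        n = 64L, kind = "growth_sensor") {
  cell <- new_cell(id, center, area = area, n_points = n)
  cell$kind <- rep(receptor_kinds[[kind]], n)
  cell
}

# random star-shaped simple polygon around a centre (deterministic per seed)
star_polygon <- function(n = 24, r0 = 5, jitter = 0.3, seed = 1,
                         center = c(0, 0)) {
  set.seed(seed)
  r <- r0 * (1 + stats::runif(n, -jitter, jitter))
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# two cells side by side, close enough to touch along one arc
abutting_pair <- function(gap = 0.5, area = pi * 5^2, n = 40L) {
  r <- sqrt(area / pi)
  c1 <- circle_cell(1L, c(20 - r - gap / 2, 20), area = area, n = n)
  c2 <- circle_cell(2L, c(20 + r + gap / 2, 20), area = area, n = n)
  tissue(list(c1, c2))
}

# a ring of `n_ring` cells whose centres sit on a circle, enclosing a hole
ring_tissue <- function(n_ring = 8, ring_radius = 14, cell_area = pi * 5.8^2,
                        center = c(30, 30)) {
  cells <- lapply(seq_len(n_ring), function(k) {
    th <- 2 * pi * (k - 1) / n_ring
    circle_cell(k, center + ring_radius * c(cos(th), sin(th)),
                area = cell_area, n = 48L)
  })
  tissue(cells)
}

# a filled block of cells (no enclosed hole)
disk_tissue <- function(center = c(30, 30), cell_area = pi * 5.8^2) {
  r <- sqrt(cell_area / pi)
  offs <- expand.grid(x = -1:1, y = -1:1)
  cells <- lapply(seq_len(nrow(offs)), function(k)
    circle_cell(k, center + 1.4 * r * c(offs$x[k], offs$y[k]),
                area = cell_area, n = 48L))
  tissue(cells)
}

# minimal trajectory wrapper for classification tests
fake_trajectory <- function(tissue, config, stabilized = TRUE) {
  structure(list(
    config = config,
    snapshots = list(final = list(day = config$t_end_days,
                                  clock = config$t_end_days * 24,
                                  tissue = tissue)),
    stabilized = stabilized
  ), class = "ib_trajectory")
}

# reference spreading oracle: direct double loop over every grid node
spread_oracle <- function(positions, values, n, h) {
  out <- matrix(0, n, n)
  for (l in seq_len(nrow(positions))) {
    for (i in seq_len(n)) {
      wx <- delta_weight(((i - 1) * h - positions[l, 1]) / h)
      if (wx == 0) {
        # periodic images
        wx <- delta_weight(((i - 1) * h - positions[l, 1] + n * h) / h) +
              delta_weight(((i - 1) * h - positions[l, 1] - n * h) / h)
      }
      if (wx == 0) next
      for (j in seq_len(n)) {
        wy <- delta_weight(((j - 1) * h - positions[l, 2]) / h)
        if (wy == 0) {
          wy <- delta_weight(((j - 1) * h - positions[l, 2] + n * h) / h) +
                delta_weight(((j - 1) * h - positions[l, 2] - n * h) / h)
        }
        out[i, j] <- out[i, j] + values[l] * wx * wy / h^2
      }
    }
  }
  out
}
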