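test_that("shoelace area handles squares, polygonal circles and orientation", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area(sq), 1)
  # regular 64-gon of circumradius 10: closed form (1/2) n R^2 sin(2 pi / n)
  n <- 64; R <- 10
  th <- 2 * pi * (seq_len(n) - 1) / n
  gon <- cbind(R * cos(th), R * sin(th))
  expect_equal(polygon_area(gon), 0.5 * n * R^2 * sin(2 * pi / n),
               tolerance = 1e-12)
  expect_equal(polygon_area(gon[rev(seq_len(n)), ]), polygon_area(gon))
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(polygon_area(bowtie, check = TRUE),
               class = "ibcell_geometry_defect")
})

test_that("membrane springs are Hookean and obey Newton's third law", {
  cell <- circle_cell(1L, c(10, 10), n = 48L)
  # construct with every edge at its rest length
  L0 <- sqrt(sum((cell$xy[2, ] - cell$xy[1, ])^2))
  f0 <- membrane_forces(cell, stiffness = 3, rest_length = L0)
  expect_lt(max(abs(f0)), 1e-10)
  # rectangle with horizontal edges stretched to 2 L0: corner force k * L0
  L <- 0.8; k <- 2.5
  rect <- list(xy = rbind(c(0, 0), c(2 * L, 0), c(2 * L, L), c(0, L)))
  class(rect) <- "ib_cell"
  fr <- membrane_forces(rect, k, L)
  expect_equal(fr[1, ], c(k * L, 0), tolerance = 1e-12)
  expect_equal(fr[2, ], c(-k * L, 0), tolerance = 1e-12)
  # arbitrary shape: forces sum to zero
  star <- list(xy = star_polygon(seed = 4))
  class(star) <- "ib_cell"
  expect_lt(max(abs(colSums(membrane_forces(star, 5, 1)))), 1e-10)
  # degenerate edge is a defect
  bad <- list(xy = rbind(c(0, 0), c(0, 0), c(1, 1)))
  class(bad) <- "ib_cell"
  expect_error(membrane_forces(bad, 1, 1), class = "ibcell_geometry_defect")
})

test_that("adhesion bonds pull with equal and opposite forces", {
  tis <- abutting_pair(gap = 0.5)
  tis <- update_adhesion(tis, d_contact = 1, d_break = 2.5, bond_rest = 0.4)
  expect_gt(nrow(tis$bonds), 0)
  f <- adhesion_forces(tis, stiffness = 2)
  tot <- Reduce(`+`, lapply(f, colSums))
  expect_lt(max(abs(tot)), 1e-10)
  # force on cell 1 balances force on its partner, bond by bond
  expect_equal(colSums(f[["1"]]), -colSums(f[["2"]]), tolerance = 1e-12)
  # a bond exactly at rest length exerts nothing
  tis2 <- tis
  tis2$bonds <- tis2$bonds[1, , drop = FALSE]
  b <- tis2$bonds
  ca <- get_cell(tis2, b$cell_a); cb <- get_cell(tis2, b$cell_b)
  tis2$bonds$rest <- sqrt(sum((ca$xy[b$idx_a, ] - cb$xy[b$idx_b, ])^2))
  f2 <- adhesion_forces(tis2, stiffness = 2)
  expect_lt(max(abs(unlist(f2))), 1e-12)
})

test_that("contractile ring forces act only on dividing cells, symmetrically", {
  cell <- circle_cell(1L, c(10, 10), n = 32L)
  expect_equal(max(abs(contractile_forces(cell, 10))), 0)
  cell$phenotype <- "dividing"
  cell$ring <- c(1L, 17L)              # across the diameter
  cell$rest_ring <- 0
  f <- contractile_forces(cell, 10)
  expect_equal(f[1, ], -f[17, ], tolerance = 1e-12)
  # force is along the diameter through both ring points
  d <- cell$xy[17, ] - cell$xy[1, ]
  expect_equal(abs(sum(f[1, ] * c(-d[2], d[1]))), 0, tolerance = 1e-10)
  cell$ring <- c(5L, 5L)
  expect_error(contractile_forces(cell, 10), class = "ibcell_invalid_ring")
})

test_that("receptor fractions are point-count shares that sum to one", {
  cell <- circle_cell(1L, n = 40L)
  expect_equal(receptor_fraction(cell, "growth_sensor"), 1)
  cell$kind[1:4] <- receptor_kinds[["death_receptor"]]
  expect_equal(receptor_fraction(cell, "death_receptor"), 0.1)
  total <- sum(vapply(names(receptor_kinds),
                      function(k) receptor_fraction(cell, k), 0))
  expect_equal(total, 1)
})

test_that("boundary resampling restores spacing and preserves area", {
  spacing <- 0.7
  cell <- circle_cell(1L, n = 64L, area = pi * 5^2)
  d0 <- sqrt(sum((cell$xy[2, ] - cell$xy[1, ])^2))
  res <- resample_boundary(cell, spacing = d0)   # already within band
  expect_identical(res$cell$xy, cell$xy)
  expect_identical(res$map, seq_len(64L))
  # one edge at twice the band maximum gets exactly one midpoint
  stretched <- cell
  keep <- c(1, 3:64)                    # drop a point to stretch edge 1-3
  stretched$xy <- cell$xy[keep, ]
  stretched$kind <- cell$kind[keep]
  stretched$ecm <- cell$ecm[keep]
  res2 <- resample_boundary(stretched, spacing = d0)
  expect_equal(nrow(res2$cell$xy), 64L)
  # a grown circle is resampled with < 0.5% area change
  big <- circle_cell(1L, n = 32L, area = pi * 8^2)
  res3 <- resample_boundary(big, spacing = 0.8)
  expect_gt(nrow(res3$cell$xy), 32)
  expect_lt(abs(polygon_area(res3$cell) - polygon_area(big)) /
              polygon_area(big), 0.005)
  # protected points survive and are tracked through the index map
  prot_res <- resample_boundary(big, spacing = 0.8, protect = 5L)
  expect_equal(prot_res$cell$xy[prot_res$map[5], ], big$xy[5, ])
})

test_that("neighbor pairing is greedy, exclusive and order-independent", {
  far <- tissue(list(circle_cell(1L, c(10, 20), area = pi * 16),
                     circle_cell(2L, c(30, 20), area = pi * 16)))
  expect_equal(nrow(neighbor_pairs(far, 1)), 0)
  tis <- abutting_pair(gap = 0.4)
  p <- neighbor_pairs(tis, d_contact = 1)
  expect_gt(nrow(p), 0)
  expect_true(all(p$dist <= 1))
  # pairs lie on the facing arcs only (near the vertical interface)
  xs <- vapply(seq_len(nrow(p)), function(r)
    get_cell(tis, p$cell_a[r])$xy[p$idx_a[r], 1], 0)
  expect_true(all(abs(xs - 20) < 2))
  # each point used at most once
  expect_false(any(duplicated(paste(p$cell_a, p$idx_a))))
  expect_false(any(duplicated(paste(p$cell_b, p$idx_b))))
  # reordering the cell list does not change the pairing
  tis_r <- tis
  tis_r$cells <- rev(tis_r$cells)
  p2 <- neighbor_pairs(tis_r, d_contact = 1)
  expect_equal(p[order(p$idx_a), c("idx_a", "idx_b")],
               p2[order(p2$idx_a), c("idx_a", "idx_b")],
               ignore_attr = TRUE)
})

test_that("self-intersection detection and untangling work on folded chains", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_false(polygon_self_intersects_cpp(sq[, 1], sq[, 2]))
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_true(polygon_self_intersects_cpp(bowtie[, 1], bowtie[, 2]))
  # a polygon with a small folded loop loses exactly the loop
  n <- 20
  th <- 2 * pi * (seq_len(n) - 1) / n
  poly <- cbind(5 * cos(th), 5 * sin(th))
  poly[3, ] <- poly[5, ] + c(0.2, 0.2)  # fold point 3 past point 5
  if (polygon_self_intersects_cpp(poly[, 1], poly[, 2])) {
    keep <- ibcell:::untangle_indices(poly, min_points = 8)
    expect_false(is.null(keep))
    expect_false(polygon_self_intersects_cpp(poly[keep, 1], poly[keep, 2]))
    expect_gte(length(keep), 8)
  }
})
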