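test_that("phenotype counts group growing/dividing vs apoptotic", {
  tis <- ring_tissue()
  tis$cells[[1]]$phenotype <- "growing"
  tis$cells[[2]]$phenotype <- "dividing"
  tis$cells[[3]]$phenotype <- "apoptotic"
  cnt <- count_phenotypes(tis)
  ph <- vapply(tis$cells, `[[`, "", "phenotype")   # brute-force scan
  expect_equal(cnt[["n_total"]], length(ph))
  expect_equal(cnt[["n_growing"]], sum(ph %in% c("growing", "dividing")))
  expect_equal(cnt[["n_dying"]], sum(ph == "apoptotic"))
  # invariant under relabelling of ids
  tis2 <- tis
  for (k in seq_along(tis2$cells)) tis2$cells[[k]]$id <- 100L + k
  names(tis2$cells) <- vapply(tis2$cells, function(c) as.character(c$id), "")
  expect_equal(count_phenotypes(tis2), cnt)
  # day-0 snapshot of a fresh run is a single viable cell
  tr0 <- run_simulation(sim_config(grid_n = 32, domain_um = 40,
                                   cell_diameter_um = 10, t_end_days = 0))
  expect_equal(tr0$counts$n_total, 1)
  expect_lte(tr0$counts$n_growing, 1)
  expect_equal(tr0$counts$n_dying, 0)
})

test_that("cluster metrics recover areas, lumens and monolayer status", {
  cfg <- sim_config(grid_n = 64, domain_um = 60, cell_diameter_um = 12)
  # single cell: cluster = cell, no lumen, trivially monolayer
  one <- tissue(list(circle_cell(1L, c(30, 30), area = pi * 36)))
  m1 <- cluster_metrics(one, cfg)
  expect_equal(m1$cluster_area_um2, pi * 36, tolerance = 0.05 * pi * 36)
  expect_equal(m1$lumen_area_um2, 0)
  expect_true(m1$monolayer)
  expect_gt(m1$roundness, 0.9)
  # a ring of cells encloses a hole of known size
  ring <- ring_tissue(n_ring = 8, ring_radius = 14)
  mr <- cluster_metrics(ring, cfg)
  expect_gt(mr$lumen_area_um2, 0)
  # geometric estimate of the hole: disc between the inner cell tangents
  hole <- pi * (14 - 5.8)^2
  expect_lt(abs(mr$lumen_area_um2 - hole) / hole, 0.6)
  expect_true(mr$monolayer)
  # a filled block has no lumen and hides its centre cell
  disk <- disk_tissue()
  md <- cluster_metrics(disk, cfg)
  expect_equal(md$lumen_area_um2, 0)
  expect_false(md$monolayer)
  expect_error(cluster_metrics(tissue(), cfg), "empty")
})

test_that("equivalent diameters reproduce the printed worked example", {
  expect_equal(equivalent_diameter(pi, 1), 2)
  expect_equal(equivalent_diameter(3490, 11.5), 19.66, tolerance = 0.001)
  pairs <- rbind(c(3490, 11.5), c(7640, 25.8), c(6180, 20.2), c(11450, 40.7))
  d <- equivalent_diameter(pairs[, 1], pairs[, 2])
  expect_true(all(d > 18.5 & d < 20.5))
  expect_equal(mean(d), 19.44, tolerance = 0.01)
})

test_that("morphology classification follows the four-class rule", {
  cfg <- sim_config(grid_n = 64, domain_um = 60, cell_diameter_um = 12,
                    t_end_days = 10)
  ring <- ring_tissue(n_ring = 8, ring_radius = 14)
  expect_equal(classify_morphology(fake_trajectory(ring, cfg)), "normal")
  disk <- disk_tissue()
  expect_equal(classify_morphology(fake_trajectory(disk, cfg)), "filled")
  expect_equal(classify_morphology(fake_trajectory(ring, cfg,
                                                   stabilized = FALSE)),
               "non_stabilized")
  # a stabilized hollow ring with an extreme outline is degenerate
  stretched <- ring_tissue(n_ring = 8, ring_radius = 14)
  for (id in names(stretched$cells)) {
    cell <- stretched$cells[[id]]
    cell$xy[, 1] <- 30 + (cell$xy[, 1] - 30) * 3.2   # strong elongation
    stretched <- set_cell(stretched, cell)
  }
  cfg2 <- sim_config(grid_n = 64, domain_um = 120, cell_diameter_um = 12,
                     t_end_days = 10)
  for (id in names(stretched$cells)) {
    cell <- stretched$cells[[id]]
    cell$xy <- cell$xy + 30
    stretched <- set_cell(stretched, cell)
  }
  expect_equal(classify_morphology(fake_trajectory(stretched, cfg2)),
               "degenerate")
  empty <- fake_trajectory(ring, cfg)
  empty$snapshots[[1]]$tissue <- tissue()
  expect_error(classify_morphology(empty), class = "ibcell_geometry_defect")
})

test_that("target-band comparison flags deviations beyond one SD", {
  sim <- data.frame(day = c(4, 8), n_total = c(11.5, 25.8),
                    n_growing = c(5, 6), n_dying = c(0, 1))
  targets <- data.frame(day = c(4, 8), total_mean = c(11.5, 25.8),
                        total_sd = c(2, 6.3))
  res <- compare_to_targets(sim, targets)
  expect_true(all(res$within_band))
  expect_equal(attr(res, "max_abs_z"), 0)
  # one day pushed to mean + 2 SD fails that day only
  sim2 <- sim; sim2$n_total[1] <- 11.5 + 2 * 2
  res2 <- compare_to_targets(sim2, targets)
  expect_false(res2$within_band[1])
  expect_true(res2$within_band[2])
  expect_equal(res2$max_abs_z[1], 2)
  # brute-force agreement of the band rule
  manual <- abs(sim2$n_total - targets$total_mean) <= targets$total_sd
  expect_equal(res2$within_band, manual)
})
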