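test_that("adhesion assembly and disassembly follow the contact distances", {
  lone <- tissue(list(circle_cell(1L, c(20, 20))))
  lone <- update_adhesion(lone, 1, 2.5)
  expect_equal(nrow(lone$bonds), 0)
  tis <- abutting_pair(gap = 0.5)
  tis <- update_adhesion(tis, 1, 2.5)
  n_b <- nrow(tis$bonds)
  expect_gt(n_b, 0)
  adh <- receptor_kinds[["adhesion_receptor"]]
  for (r in seq_len(n_b)) {
    expect_identical(get_cell(tis, tis$bonds$cell_a[r])$kind[tis$bonds$idx_a[r]],
                     adh)
    expect_identical(get_cell(tis, tis$bonds$cell_b[r])$kind[tis$bonds$idx_b[r]],
                     adh)
  }
  # outer arcs stay free sensors
  c1 <- get_cell(tis, 1)
  left_arc <- c1$xy[, 1] < 12
  expect_true(all(c1$kind[left_arc] == receptor_kinds[["growth_sensor"]]))
  # pulling the cells apart breaks every bond and reverts the receptors
  tis2 <- tis
  c2 <- get_cell(tis2, 2)
  c2$xy[, 1] <- c2$xy[, 1] + 10
  tis2 <- set_cell(tis2, c2)
  tis2 <- update_adhesion(tis2, 1, 2.5)
  expect_lte(nrow(tis2$bonds), n_b)
  expect_equal(nrow(tis2$bonds), 0)
  expect_true(all(get_cell(tis2, 2)$kind ==
                    receptor_kinds[["growth_sensor"]]))
})

test_that("ECM receptor conversion is a memoryless threshold rule", {
  tis <- tissue(list(circle_cell(1L, c(20, 20))))
  cell <- get_cell(tis, 1)
  set.seed(9)
  cell$ecm <- runif(nrow(cell$xy), 0, 20)
  tis <- set_cell(tis, cell)
  expect_equal(sum(get_cell(update_ecm_receptors(tis, Inf), 1)$kind ==
                     receptor_kinds[["ecm_receptor"]]), 0)
  E <- 12
  tis2 <- update_ecm_receptors(tis, E)
  got <- get_cell(tis2, 1)$kind == receptor_kinds[["ecm_receptor"]]
  expect_identical(got, cell$ecm >= E)   # brute-force threshold scan
  # decaying below E reverts
  c2 <- get_cell(tis2, 1)
  c2$ecm[] <- 0
  tis3 <- update_ecm_receptors(set_cell(tis2, c2), E)
  expect_true(all(get_cell(tis3, 1)$kind ==
                    receptor_kinds[["growth_sensor"]]))
})

test_that("growth decision gates on the free-sensor fraction and rule flags", {
  cell <- circle_cell(1L, n = 40L)
  expect_equal(decide_growth(cell, 0), "growing")
  cell$kind[] <- receptor_kinds[["adhesion_receptor"]]
  cell$kind[1:8] <- receptor_kinds[["growth_sensor"]]   # 20% free
  expect_equal(decide_growth(cell, 25), "contact_inhibited")
  expect_equal(decide_growth(cell, 15), "growing")
  # luminal-space sensing lets apical markers count as free
  cell$kind[9:12] <- receptor_kinds[["apical_marker"]]  # + 10% apical
  expect_equal(decide_growth(cell, 25), "contact_inhibited")
  expect_equal(decide_growth(cell, 25, list(lumen_sensing = TRUE)), "growing")
  # releasing contact inhibition lets adhered membrane count as well
  expect_equal(decide_growth(cell, 95,
                             list(contact_inhibition_released = TRUE,
                                  lumen_sensing = TRUE)), "growing")
})

test_that("growth sources balance per cell and pump at the nominal rate", {
  cell <- circle_cell(1L, c(20, 20))
  expect_equal(length(place_growth_sources(cell, 10, 1)$strength), 0)
  cell$phenotype <- "growing"
  src <- place_growth_sources(cell, 10, 1)
  expect_gt(length(src$strength), 0)
  expect_equal(sum(src$strength), 0, tolerance = 1e-12)
  # a lone free cell grown for one hour gains area within 10% of the rate
  cfg <- sim_config(grid_n = 64, domain_um = 40, cell_diameter_um = 10,
                    G = 0, E = 1e9, source_strength = 12, t_end_days = 1)
  st <- init_state(cfg)
  a0 <- polygon_area(st$tissue$cells[[1]])
  while (st$clock < 1) st <- sim_step(st)
  gain <- polygon_area(st$tissue$cells[[1]]) - a0
  expect_lt(abs(gain - 12) / 12, 0.1)
})

test_that("ECM kinetics reach secretion/decay at basal points and decay elsewhere", {
  tis <- tissue(list(circle_cell(1L, c(20, 20), n = 16L)))
  basal <- list("1" = c(rep(TRUE, 8), rep(FALSE, 8)))
  secr <- 0.3; dec <- 0.05; dt <- 0.05
  c0 <- get_cell(tis, 1)
  c0$ecm <- rep(2, 16)
  tis <- set_cell(tis, c0)
  for (k in seq_len(2400)) tis <- update_ecm_field(tis, secr, dec, dt, basal)
  ecm <- get_cell(tis, 1)$ecm
  expect_equal(ecm[1], secr / dec, tolerance = 0.01)           # steady state
  expect_equal(ecm[16], 2 * exp(-dec * 120), tolerance = 0.02)  # decay law
  # zero decay, non-basal: concentration is conserved
  tis2 <- update_ecm_field(tis, secr, 0, 5, list("1" = rep(FALSE, 16)))
  expect_equal(get_cell(tis2, 1)$ecm, ecm, tolerance = 1e-12)
})

test_that("the division trigger fires at doubled area with a lawful ring", {
  cell <- circle_cell(1L, c(20, 20), area = pi * 25, n = 40L)
  cell$rest_area <- pi * 25
  cell$phenotype <- "growing"
  expect_identical(check_division(cell, 1, 8)$phenotype, "growing")  # 1x area
  grown <- circle_cell(1L, c(20, 20), area = 2.05 * pi * 25, n = 40L)
  grown$rest_area <- pi * 25
  grown$phenotype <- "growing"
  d <- check_division(grown, 1, 8)
  expect_identical(d$phenotype, "dividing")
  expect_identical(d$ring, c(1L, 21L))   # lowest-index diameter tie-break
  sep <- (d$ring[2] - d$ring[1]) %% 40
  expect_gte(min(sep, 40 - sep), 10)     # no sliver daughters
  # basal-guided early division splits the basal arc between both daughters
  basal <- rep(FALSE, 40); basal[1:11] <- TRUE
  d2 <- check_division(grown, 4, 8, basal = basal)
  expect_identical(d2$ring, sort(c(6L, 26L)))  # basal midpoint + antipode
})

test_that("splitting a pinched cell conserves area and resets the daughters", {
  mother <- circle_cell(7L, c(20, 20), area = 2 * pi * 25, n = 48L)
  mother$rest_area <- pi * 25
  mother$phenotype <- "dividing"
  mother$ring <- c(1L, 25L)
  mother$rest_ring <- 0
  kids <- split_cell(mother, next_id = 8L, now = 30, maturation = 4,
                     spacing = 0.8)
  expect_length(kids, 2)
  expect_identical(vapply(kids, `[[`, 0L, "id"), c(8L, 9L))
  a <- vapply(kids, polygon_area, 0)
  expect_equal(sum(a), polygon_area(mother), tolerance = 0.01)
  expect_true(all(a / polygon_area(mother) > 0.35 &
                    a / polygon_area(mother) < 0.65))
  for (k in kids) {
    expect_true(all(k$kind == receptor_kinds[["growth_sensor"]]))
    expect_identical(k$phenotype, "resting")
    expect_equal(k$maturation, 4)
    expect_equal(k$birth_time, 30)
    expect_false(polygon_self_intersects_cpp(k$xy[, 1], k$xy[, 2]))
  }
})

test_that("apoptosis needs the death-receptor threshold plus its delay", {
  tis <- tissue(list(circle_cell(1L, c(20, 20), n = 20L)))
  cell <- get_cell(tis, 1)
  cell$kind[1:10] <- receptor_kinds[["death_receptor"]]
  tis <- set_cell(tis, cell)
  # D = 100 with only half the membrane converted never triggers
  t2 <- update_apoptosis(tis, D = 100, death_delay = 1, rule_dt = 10)
  expect_identical(get_cell(t2, 1)$phenotype, "resting")
  # D = 10: triggers only after the delay accumulates
  t3 <- update_apoptosis(tis, D = 10, death_delay = 4, rule_dt = 2)
  expect_identical(get_cell(t3, 1)$phenotype, "resting")
  t4 <- update_apoptosis(t3, D = 10, death_delay = 4, rule_dt = 2)
  expect_identical(get_cell(t4, 1)$phenotype, "apoptotic")
  # a drained cell is removed and logged
  c4 <- get_cell(t4, 1)
  ctr <- colMeans(c4$xy)
  c4$xy <- sweep(sweep(c4$xy, 2, ctr), 1, rep(0.2, nrow(c4$xy)), `*`) +
    rep(1, nrow(c4$xy)) %o% ctr
  t5 <- update_apoptosis(set_cell(t4, c4), D = 10, death_delay = 4,
                         rule_dt = 2, now = 55)
  expect_equal(n_cells(t5), 0)
  expect_equal(t5$removed_log$cell_id, 1L)
  expect_equal(t5$removed_log$time, 55)
})

test_that("a shelled cluster polarizes outward-in and marks the core for death", {
  # centre cell hexagonally surrounded by six ECM-committed outer cells,
  # each touching the centre and both ring neighbours
  r <- 5
  area <- pi * r^2
  th <- 2 * pi * (0:5) / 6
  # slight overlap so the rasterized shell seals the centre off completely
  centers <- rbind(c(0, 0), cbind((2 * r - 0.6) * cos(th),
                                  (2 * r - 0.6) * sin(th)))
  cells <- lapply(1:7, function(k)
    circle_cell(k, c(40, 40) + centers[k, ], area = area, n = 48L))
  tis <- tissue(cells)
  cfg <- sim_config(grid_n = 64, domain_um = 80, cell_diameter_um = 10)
  cls <- classify_points(tis, cfg)
  expect_false(cls$outer[["1"]])                       # centre is inner
  expect_true(all(cls$outer[as.character(2:7)]))       # shell is outer
  tis <- update_adhesion(tis, cfg$d_contact_um, cfg$d_break_um,
                         cfg$bond_rest_um, cls = cls)
  expect_gt(nrow(tis$bonds), 0)
  # commit the shell's basal domains to the matrix
  for (k in 2:7) {
    cell <- get_cell(tis, k)
    cell$ecm[cls$basal[[as.character(k)]]] <- 99
    tis <- set_cell(tis, cell)
  }
  tis <- update_ecm_receptors(tis, E = 50)
  # two rule passes of 2 h each against a 4 h apical delay
  cls <- classify_points(tis, cfg)
  tis <- update_polarization(tis, apical_delay = 4, cls, rule_dt = 2)
  expect_false(any(vapply(tis$cells, `[[`, TRUE, "polarized")[
    as.character(2:7)]))
  tis <- update_polarization(tis, apical_delay = 4, cls, rule_dt = 2)
  pol <- vapply(tis$cells, `[[`, TRUE, "polarized")
  expect_true(any(pol[as.character(2:7)]))
  expect_false(pol[["1"]])
  # the centre cell lost its bonds to polarized cells and carries death
  # receptors; apical points never carry bonds
  inner <- get_cell(tis, 1)
  expect_gt(sum(inner$kind == receptor_kinds[["death_receptor"]]), 0)
  ap <- receptor_kinds[["apical_marker"]]
  for (r_ in seq_len(nrow(tis$bonds))) {
    ka <- get_cell(tis, tis$bonds$cell_a[r_])$kind[tis$bonds$idx_a[r_]]
    kb <- get_cell(tis, tis$bonds$cell_b[r_])$kind[tis$bonds$idx_b[r_]]
    expect_false(ka == ap || kb == ap)
  }
})
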