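#' Study-condition configuration presets
#'
#' Ready-made configurations for the simulated study conditions:
#'
#' * `config_mcf10a()` - the tuned non-tumorigenic baseline: hollow-acinus
#'   thresholds `V = (25, 10, 14.5)`, growth calibrated so the effective
#'   (population-mean) doubling time is about 48 h, on a 160 um box
#'   (a day-8 acinus is ~100 um across and must stay clear of the
#'   periodic wrap).
#' * `config_yvma()` - the HER2-YVMA-like mutant: thresholds
#'   `V = (0, 65, 15)`, contact inhibition released and luminal-space
#'   sensing enabled, and a larger fluid source strength that shortens the
#'   effective doubling time to about 33 h.
#' * `config_mini()` - a miniaturized geometry (12 um cells, 80 um box,
#'   64 grid) used for qualitative morphology classification suites where
#'   absolute sizes do not matter; ECM kinetics keep the same steady state.
#' * `config_toy()` - a very small, fast-growing setup for tuner and
#'   property tests (hours-scale horizons).
#'
#' @param ... overrides forwarded to [sim_config()].
#' @return an `ib_config`.
#' @name presets
NULL

#' @rdname presets
#' @export
config_mcf10a <- function(...) {
  sim_config(
    grid_n = 128L, domain_um = 160,
    G = 25, D = 10, E = 14.5,
    cell_diameter_um = 17,
    source_strength = 29,
    maturation_h = 6,
    apoptosis_rate = 15,
    death_delay_h = 20,
    apical_delay_h = 48,
    t_end_days = 20,
    ...
  )
}

#' @rdname presets
#' @export
config_yvma <- function(...) {
  sim_config(
    grid_n = 128L, domain_um = 160,
    G = 0, D = 65, E = 15,
    cell_diameter_um = 17,
    source_strength = 44,
    maturation_h = 6,
    apoptosis_rate = 15,
    death_delay_h = 20,
    apical_delay_h = 48,
    lumen_sensing = TRUE,
    contact_inhibition_released = TRUE,
    t_end_days = 24,
    ...
  )
}

#' @rdname presets
#' @export
config_mini <- function(...) {
  sim_config(
    grid_n = 64L, domain_um = 80,
    cell_diameter_um = 12,
    source_strength = 8,
    maturation_h = 6,
    t_end_days = 16,
    ...
  )
}

#' @rdname presets
#' @export
config_toy <- function(...) {
  sim_config(
    grid_n = 64L, domain_um = 60,
    cell_diameter_um = 10,
    spacing_um = 0.7,
    source_strength = 12,
    maturation_h = 2,
    t_end_days = 2,
    ...
  )
}
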