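# Long simulations shared between acceptance criteria; computed once per
# suite run and cached.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, maker) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- maker()
  .run_cache[[key]]
}

mcf10a_trajectory <- function() {
  cached_run("mcf10a", function() run_simulation(config_mcf10a()))
}

yvma_trajectory <- function() {
  cached_run("yvma", function()
    run_simulation(config_yvma(t_end_days = 8, day_schedule = c(0, 4, 8))))
}

toy_base_trajectory <- function() {
  cached_run("toy", function()
    run_simulation(config_toy(t_end_days = 3, day_schedule = c(0, 1, 2, 3))))
}

# tuner menu used in tests: fluid source strength only (the day-4 knob)
source_only_menu <- function() {
  data.frame(key = "source_strength", stage = "early", kind = "rel",
             step = 0.2)
}
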