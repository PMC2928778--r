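config_defaults <- function() {
  list(
    # fluid grid
    grid_n = 128L,          # nodes per axis (power of two)
    domain_um = 80,         # periodic box edge, um
    mu = 1,                 # fluid viscosity (force units / velocity scale)
    rho = 0,                # 0 = quasi-static Stokes regime
    # time stepping
    dt_h = 0.1,             # mechanics step, hours
    rule_dt_h = 0.2,        # receptor/phenotype rule cadence, hours
    # receptor thresholds V = (G, D, E)
    G = 25,                 # growth-sensor fraction threshold, percent
    D = 10,                 # death-receptor fraction threshold, percent
    E = 14.5,               # ECM density threshold, concentration units
    # cell geometry
    cell_diameter_um = 20,  # typical (daughter/resting) cell diameter
    n_points_init = NULL,   # boundary points on the initial cell
                            # (default: circumference / spacing)
    spacing_um = 0.6,       # target boundary point spacing (~h/2)
    # membrane / adhesion mechanics
    k_membrane = 4,         # edge spring constant, force/um
    k_adhesion = 4,         # bond spring constant, force/um
    k_ring = 12,            # contractile-ring spring constant
    bond_rest_um = 0.4,     # adhesion bond rest length
    d_contact_um = 1.0,     # bond assembly distance
    d_break_um = 2.5,       # bond disassembly distance
    ring_rate_um_h = 8,     # contractile-ring rest-length shrink rate
    max_division_h = 16,    # force the geometric split after this long
    # growth / death kinetics
    source_strength = 10,   # area gain rate of a fully free cell, um^2/h
    apoptosis_rate = NULL,  # drain rate of a dying cell, um^2/h
                            # (default: equal to source_strength)
    maturation_h = 4,       # post-division rest before growth eligibility
    apical_delay_h = 4,     # delay before apical markers emerge
    death_delay_h = 4,      # delay before the cytoskeleton collapses
    detach_delay_h = 4,     # delay before a dying cell sheds its bonds
    division_mode_switch = 8L,  # tissue size at which division turns asymmetric
    # ECM kinetics (per boundary point)
    ecm_secretion = 0.1355, # concentration / h along basal domains
    ecm_decay = 0.00542,    # 1 / h everywhere
    # rule switches
    lumen_sensing = FALSE,            # apical markers count as free space
    contact_inhibition_released = FALSE,  # adhesion receptors count as free
    # schedule
    t_end_days = 20,
    day_schedule = NULL,    # default: every day 0..t_end
    stabilization_window_days = 2,
    grace_days = 1,
    seam_margin_um = 2      # abort if the tissue gets this close to the wrap
  )
}

#' Simulation configuration
#'
#' Builds a validated configuration from the documented defaults plus
#' overrides. The threshold triple `V = (G, D, E)` gates growth (minimum free
#' growth-sensor percentage), apoptosis (minimum death-receptor percentage)
#' and ECM-receptor conversion (local matrix density); the remaining keys are
#' mechanical and kinetic calibration constants described in the package
#' vignette. Unknown keys are rejected.
#'
#' @param ... named overrides of the default keys.
#' @return an object of class `ib_config` (a named list).
#' @export
sim_config <- function(...) {
  cfg <- config_defaults()
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all configuration overrides must be named")
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  num_pos <- c("domain_um", "mu", "dt_h", "rule_dt_h", "cell_diameter_um",
               "spacing_um", "k_membrane", "k_adhesion", "k_ring",
               "d_contact_um", "d_break_um", "ring_rate_um_h",
               "max_division_h", "source_strength", "seam_margin_um")
  for (k in num_pos)
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || cfg[[k]] <= 0)
      stop("configuration key `", k, "` must be a positive number")
  num_nonneg <- c("rho", "E", "bond_rest_um", "maturation_h", "apical_delay_h",
                  "death_delay_h", "detach_delay_h", "ecm_secretion",
                  "ecm_decay", "t_end_days", "stabilization_window_days",
                  "grace_days")
  for (k in num_nonneg)
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || cfg[[k]] < 0)
      stop("configuration key `", k, "` must be a non-negative number")
  for (k in c("G", "D"))
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0 || cfg[[k]] > 100)
      stop("threshold `", k, "` must lie in [0, 100] (percent)")
  cfg$grid_n <- as.integer(cfg$grid_n)
  if (bitwAnd(cfg$grid_n, cfg$grid_n - 1L) != 0L || cfg$grid_n < 16L)
    stop("grid_n must be a power of two >= 16")
  if (cfg$d_break_um < cfg$d_contact_um)
    stop("d_break_um must be >= d_contact_um")
  if (is.null(cfg$apoptosis_rate)) cfg$apoptosis_rate <- cfg$source_strength
  if (!is.numeric(cfg$apoptosis_rate) || cfg$apoptosis_rate <= 0)
    stop("apoptosis_rate must be a positive number")
  if (is.null(cfg$n_points_init))
    cfg$n_points_init <- max(24L, as.integer(round(
      pi * cfg$cell_diameter_um / cfg$spacing_um)))
  cfg$n_points_init <- as.integer(cfg$n_points_init)
  cfg$division_mode_switch <- as.integer(cfg$division_mode_switch)
  if (cfg$n_points_init < 16L) stop("n_points_init must be >= 16")
  for (k in c("lumen_sensing", "contact_inhibition_released"))
    if (!is.logical(cfg[[k]]) || length(cfg[[k]]) != 1 || is.na(cfg[[k]]))
      stop("flag `", k, "` must be TRUE or FALSE")
  if (is.null(cfg$day_schedule))
    cfg$day_schedule <- seq(0, cfg$t_end_days)
  cfg$day_schedule <- sort(unique(as.numeric(cfg$day_schedule)))
  if (any(cfg$day_schedule < 0) || any(cfg$day_schedule > cfg$t_end_days))
    stop("day_schedule must lie within [0, t_end_days]")
  class(cfg) <- "ib_config"
  cfg
}

#' @export
print.ib_config <- function(x, ...) {
  cat(sprintf("<ib_config> V = (G=%g%%, D=%g%%, E=%g), grid %dx%d over %g um\n",
              x$G, x$D, x$E, x$grid_n, x$grid_n, x$domain_um))
  cat(sprintf("  dt = %g h, t_end = %g d, source = %g um^2/h, flags: %s%s\n",
              x$dt_h, x$t_end_days, x$source_strength,
              if (x$lumen_sensing) "lumen_sensing " else "",
              if (x$contact_inhibition_released) "ci_released" else ""))
  invisible(x)
}

#' Stable hash of a configuration
#'
#' Stamped into trajectories, snapshots and manifests so any output can be
#' traced to the exact configuration that produced it.
#'
#' @param config an `ib_config`.
#' @return an md5 string.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "ib_config"))
  f <- tempfile()
  on.exit(unlink(f))
  keys <- sort(names(unclass(config)))
  writeLines(vapply(keys, function(k)
    paste(k, paste(format(config[[k]], digits = 17), collapse = ","),
          sep = "="), character(1)), f)
  unname(tools::md5sum(f))
}

#' Read a configuration file
#'
#' Flat key-value YAML; missing keys take their defaults, unknown keys are
#' rejected with the offending name.
#'
#' @param path file path.
#' @return an `ib_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("configuration file must be a key-value mapping")
  do.call(sim_config, raw)
}

#' Write a configuration file
#'
#' @param config an `ib_config`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ib_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
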