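# YAML run configuration: defaults, validation, round-trip.

config_defaults <- function() {
  cfg <- lcpm_config()
  list(
    L = cfg$L, alpha = cfg$alpha, H = cfg$H,
    sigma = cfg$sigma, gamma = cfg$gamma, transform_scope = cfg$transform_scope,
    youngs_modulus = cfg$material$youngs_modulus,
    poisson_ratio = cfg$material$poisson_ratio,
    max_principal_stress = cfg$material$max_principal_stress,
    fracture_energy = cfg$material$fracture_energy,
    patch_radius = cfg$load$patch_radius, patch_offset = cfg$load$patch_offset,
    ramp_cap = NA, ramp_steps = cfg$load$ramp_steps,
    ramp_safety = cfg$load$ramp_safety,
    gap_max = cfg$gap_max, merge_tol = cfg$merge_tol,
    closure_eps = cfg$closure_eps, max_windows = cfg$max_windows,
    seed_len = cfg$seed_len, sweep_N = cfg$sweep_N, sweep_m = cfg$sweep_m,
    canny_low = cfg$canny_low, canny_high = cfg$canny_high,
    probe_max = cfg$probe_max, probe_frac = cfg$probe_frac,
    max_respawns = cfg$max_respawns)
}

#' Load a run configuration from YAML
#'
#' Reads a flat YAML file of parameter overrides, validates every key and
#' range, and returns the corresponding [lcpm_config()]. Unknown keys are
#' rejected so typos fail loudly; an empty or missing-field file yields all
#' defaults.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Named list applied on top of the file (highest
#'   precedence, used by the command-line interface).
#' @return An `lcpm_config` with attribute `echo`: the fully resolved flat
#'   parameter list, suitable for writing alongside outputs.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_input(sprintf("config file not found: %s", path))
    y <- yaml::read_yaml(path)
    if (is.null(y)) y <- list()
    unknown <- setdiff(names(y), names(vals))
    if (length(unknown))
      stop_param(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
    vals[names(y)] <- y
  }
  unknown <- setdiff(names(overrides), names(vals))
  if (length(unknown))
    stop_param(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  vals[names(overrides)] <- overrides

  if (!is.na(vals$alpha) && (vals$alpha <= 0 || vals$alpha >= 2 * vals$L))
    stop_param(sprintf(
      "`alpha` out of range: 0 < alpha < 2L required (alpha = %s, L = %s)",
      format(vals$alpha), format(vals$L)))
  cfg <- lcpm_config(
    L = vals$L, alpha = vals$alpha, H = vals$H, sigma = vals$sigma,
    gamma = vals$gamma, transform_scope = vals$transform_scope,
    material = material_params(vals$youngs_modulus, vals$poisson_ratio,
                               vals$max_principal_stress, vals$fracture_energy),
    load = load_spec(vals$patch_radius, vals$patch_offset,
                     if (is.na(vals$ramp_cap)) NULL else vals$ramp_cap,
                     vals$ramp_steps, vals$ramp_safety),
    gap_max = vals$gap_max, merge_tol = vals$merge_tol,
    closure_eps = vals$closure_eps, max_windows = vals$max_windows,
    seed_len = vals$seed_len, sweep_N = vals$sweep_N, sweep_m = vals$sweep_m,
    canny_low = vals$canny_low, canny_high = vals$canny_high,
    probe_max = vals$probe_max, probe_frac = vals$probe_frac,
    max_respawns = vals$max_respawns)
  attr(cfg, "echo") <- vals
  cfg
}

#' Write the resolved configuration next to run outputs
#'
#' @param config An `lcpm_config` (from [load_config()] or [lcpm_config()]).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  echo <- attr(config, "echo")
  if (is.null(echo)) {
    echo <- config_defaults()
    flat <- list(L = config$L, alpha = config$alpha, H = config$H,
                 sigma = config$sigma, gamma = config$gamma,
                 transform_scope = config$transform_scope,
                 youngs_modulus = config$material$youngs_modulus,
                 poisson_ratio = config$material$poisson_ratio,
                 max_principal_stress = config$material$max_principal_stress,
                 fracture_energy = config$material$fracture_energy,
                 patch_radius = config$load$patch_radius,
                 patch_offset = config$load$patch_offset,
                 ramp_cap = if (is.null(config$load$ramp_cap)) NA else config$load$ramp_cap,
                 ramp_steps = config$load$ramp_steps,
                 ramp_safety = config$load$ramp_safety,
                 gap_max = config$gap_max, merge_tol = config$merge_tol,
                 closure_eps = config$closure_eps, max_windows = config$max_windows,
                 seed_len = config$seed_len, sweep_N = config$sweep_N,
                 sweep_m = config$sweep_m, canny_low = config$canny_low,
                 canny_high = config$canny_high, probe_max = config$probe_max,
                 probe_frac = config$probe_frac, max_respawns = config$max_respawns)
    echo[names(flat)] <- flat
  }
  yaml::write_yaml(echo, path)
  invisible(path)
}
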