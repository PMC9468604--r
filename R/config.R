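#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline with their defaults: the
#' 3.0 Angstrom salt-bridge cutoff, the 8 percent barcode occupancy floor,
#' the 1 Angstrom equilibration tolerance and the 0.05 significance level
#' are the conventions of the analyses this package implements; probe
#' radius, sphere sampling density, surface-tension coefficient and the
#' 10 kcal/mol neutrality band are package choices, documented in the
#' methods vignette.
#'
#' @param cutoff_angstrom salt-bridge heavy-atom cutoff (Angstrom).
#' @param min_occupancy barcode occupancy floor (fraction).
#' @param equil_tol_angstrom equilibration window tolerance (Angstrom).
#' @param sasa_probe SASA probe radius (Angstrom).
#' @param sasa_points SASA sphere sample points per atom.
#' @param gamma nonpolar surface tension, kcal/(mol Angstrom^2).
#' @param alpha significance level for correlation flags.
#' @param neutrality_band heterodimer-preference neutral zone (kcal/mol).
#' @param seed RNG seed for the generators.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(cutoff_angstrom = 3.0, min_occupancy = 0.08,
                       equil_tol_angstrom = 1.0, sasa_probe = 1.4,
                       sasa_points = 960, gamma = 0.00542, alpha = 0.05,
                       neutrality_band = 10, seed = 1) {
  cfg <- list(
    cutoff_angstrom = cutoff_angstrom, min_occupancy = min_occupancy,
    equil_tol_angstrom = equil_tol_angstrom, sasa_probe = sasa_probe,
    sasa_points = as.integer(sasa_points), gamma = gamma, alpha = alpha,
    neutrality_band = neutrality_band, seed = as.integer(seed)
  )
  check_pos <- c("cutoff_angstrom", "equil_tol_angstrom", "sasa_probe", "sasa_points", "gamma")
  for (key in check_pos) {
    if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1 || cfg[[key]] <= 0) {
      abort(sprintf("invalid config value for '%s': must be a positive number", key))
    }
  }
  for (key in c("min_occupancy", "alpha")) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] < 0 || cfg[[key]] > 1) {
      abort(sprintf("invalid config value for '%s': must lie in [0, 1]", key))
    }
  }
  if (cfg$neutrality_band < 0) abort("invalid config value for 'neutrality_band': must be >= 0")
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (key in names(x)) cat(sprintf("  %-20s %s\n", key, format(x[[key]])))
  invisible(x)
}

config_header_lines <- function(config) {
  if (is.null(config)) return(character(0))
  vapply(names(config), function(key) sprintf("# %s = %s", key, format(config[[key]])), "")
}
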