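#' Simulation configuration for the synthetic proteomics generator
#'
#' Collects and validates every knob of the generative model used by
#' [simulate_design()] and [simulate_abundance()]. The generative model is the
#' exact counterpart of the fitted one: per-protein negative binomial counts
#' with a log link, a sample-specific library-size multiplier, fixed effects of
#' treatment (CON/PRU), gestation group and fetal sex in reference-level
#' (treatment-contrast) coding, and an optional zero-inflation component whose
#' logit-scale linear predictor may contain the same factors.
#'
#' @param n_per_treatment Animals per treatment arm (default 12, a 24-cow
#'   trial).
#' @param n_gestation_groups Number of gestation groups (default 3).
#' @param fetal_sex_levels Number of fetal sex levels (default 2).
#' @param n_proteins Number of proteins to simulate.
#' @param library_size_range Length-2 positive range; per-sample library sizes
#'   are drawn log-uniformly over it.
#' @param baseline_log_mean,baseline_log_sd Mean and SD of the per-protein
#'   baseline abundance intercept on the natural-log scale (relative to a unit
#'   library-size multiplier).
#' @param effect_treatment Log-scale PRU-vs-CON effect on abundance; either a
#'   scalar applied to every protein or a vector of length `n_proteins`.
#' @param effect_gestation,effect_sex Log-scale effect vectors for the
#'   non-reference levels of gestation group and fetal sex
#'   (lengths `n_gestation_groups - 1` and `fetal_sex_levels - 1`).
#' @param dispersion Negative binomial size parameter \eqn{\theta}
#'   (variance \eqn{\mu + \mu^2/\theta}); larger means less overdispersed.
#' @param zi_model Zero-inflation structure: `"none"`, `"basic"` (intercept
#'   only), `"trt"` (intercept + treatment) or `"full"` (intercept +
#'   treatment + gestation group + fetal sex).
#' @param zi_intercept Logit-scale intercept of the structural-zero
#'   probability.
#' @param zi_effect_treatment,zi_effect_gestation,zi_effect_sex Logit-scale
#'   zero-inflation effects; must be zero for terms not included in
#'   `zi_model`.
#' @param frac_contaminant,frac_reverse,frac_only_by_site Expected fractions
#'   of proteins carrying each MaxQuant-style QC flag.
#' @param seed Integer seed; identical configurations produce byte-identical
#'   output.
#'
#' @return An object of class `"sim_config"` (a validated list).
#' @seealso [simulate_design()], [simulate_abundance()], [simulate_study()]
#' @export
sim_config <- function(n_per_treatment = 12,
                       n_gestation_groups = 3,
                       fetal_sex_levels = 2,
                       n_proteins = 500,
                       library_size_range = c(5e4, 2e5),
                       baseline_log_mean = 0,
                       baseline_log_sd = 1,
                       effect_treatment = 0,
                       effect_gestation = numeric(n_gestation_groups - 1),
                       effect_sex = numeric(fetal_sex_levels - 1),
                       dispersion = 10,
                       zi_model = c("none", "basic", "trt", "full"),
                       zi_intercept = -2,
                       zi_effect_treatment = 0,
                       zi_effect_gestation = numeric(n_gestation_groups - 1),
                       zi_effect_sex = numeric(fetal_sex_levels - 1),
                       frac_contaminant = 0,
                       frac_reverse = 0,
                       frac_only_by_site = 0,
                       seed = 1L) {
  zi_model <- match.arg(zi_model)

  chk_count <- function(x, field) {
    if (length(x) != 1 || !is.finite(x) || x < 1 || x != round(x))
      config_error(field, "must be a single integer >= 1")
  }
  chk_count(n_per_treatment, "n_per_treatment")
  chk_count(n_gestation_groups, "n_gestation_groups")
  chk_count(fetal_sex_levels, "fetal_sex_levels")
  chk_count(n_proteins, "n_proteins")

  if (length(library_size_range) != 2 || any(!is.finite(library_size_range)) ||
      any(library_size_range <= 0) ||
      library_size_range[1] > library_size_range[2])
    config_error("library_size_range", "must be two strictly positive values (min, max)")
  if (!is.finite(baseline_log_mean))
    config_error("baseline_log_mean", "must be finite")
  if (!is.finite(baseline_log_sd) || baseline_log_sd < 0)
    config_error("baseline_log_sd", "must be a nonnegative real")
  if (!(length(effect_treatment) %in% c(1L, n_proteins)) ||
      any(!is.finite(effect_treatment)))
    config_error("effect_treatment", "must be a finite scalar or a vector of length n_proteins")
  if (length(effect_gestation) != n_gestation_groups - 1)
    config_error("effect_gestation",
                 sprintf("must have length %d (number of levels - 1)", n_gestation_groups - 1))
  if (length(effect_sex) != fetal_sex_levels - 1)
    config_error("effect_sex",
                 sprintf("must have length %d (number of levels - 1)", fetal_sex_levels - 1))
  if (length(dispersion) != 1 || !is.finite(dispersion) || dispersion <= 0)
    config_error("dispersion", "must be a single positive real (NB size parameter)")
  if (length(zi_effect_gestation) != n_gestation_groups - 1)
    config_error("zi_effect_gestation",
                 sprintf("must have length %d (number of levels - 1)", n_gestation_groups - 1))
  if (length(zi_effect_sex) != fetal_sex_levels - 1)
    config_error("zi_effect_sex",
                 sprintf("must have length %d (number of levels - 1)", fetal_sex_levels - 1))
  chk_frac <- function(x, field) {
    if (length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
      config_error(field, "must be a proportion in [0, 1]")
  }
  chk_frac(frac_contaminant, "frac_contaminant")
  chk_frac(frac_reverse, "frac_reverse")
  chk_frac(frac_only_by_site, "frac_only_by_site")
  if (length(seed) != 1 || !is.finite(seed) || seed != round(seed))
    config_error("seed", "must be a single integer")

  # zi_model must be consistent with the supplied ZI effects
  nonzero <- function(x) any(x != 0)
  if (zi_model == "none" &&
      (nonzero(zi_effect_treatment) || nonzero(zi_effect_gestation) ||
       nonzero(zi_effect_sex)))
    config_error("zi_model", "is \"none\" but zero-inflation effects are nonzero")
  if (zi_model == "basic" &&
      (nonzero(zi_effect_treatment) || nonzero(zi_effect_gestation) ||
       nonzero(zi_effect_sex)))
    config_error("zi_model", "is \"basic\" but non-intercept zero-inflation effects are nonzero")
  if (zi_model == "trt" &&
      (nonzero(zi_effect_gestation) || nonzero(zi_effect_sex)))
    config_error("zi_model", "is \"trt\" but gestation/sex zero-inflation effects are nonzero")

  structure(list(
    n_per_treatment = as.integer(n_per_treatment),
    n_gestation_groups = as.integer(n_gestation_groups),
    fetal_sex_levels = as.integer(fetal_sex_levels),
    n_proteins = as.integer(n_proteins),
    library_size_range = as.numeric(library_size_range),
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    effect_treatment = effect_treatment,
    effect_gestation = effect_gestation,
    effect_sex = effect_sex,
    dispersion = dispersion,
    zi_model = zi_model,
    zi_intercept = zi_intercept,
    zi_effect_treatment = zi_effect_treatment,
    zi_effect_gestation = zi_effect_gestation,
    zi_effect_sex = zi_effect_sex,
    frac_contaminant = frac_contaminant,
    frac_reverse = frac_reverse,
    frac_only_by_site = frac_only_by_site,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: %d proteins, %d animals/treatment, %d gestation groups, %d sexes\n",
    x$n_proteins, x$n_per_treatment, x$n_gestation_groups, x$fetal_sex_levels))
  cat(sprintf("  dispersion (NB size) = %g, zero-inflation = %s, seed = %d\n",
              x$dispersion, x$zi_model, x$seed))
  invisible(x)
}
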