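#' Simulate a two-treatment experimental design sheet
#'
#' Builds a per-animal design table for a balanced two-arm feeding trial:
#' `n_per_treatment` animals in each of CON and PRU, gestation group and fetal
#' sex assigned by a seeded draw that keeps the levels as balanced as possible
#' within each arm (mirroring blocked randomization), and an initial body
#' weight drawn around 545 +/- 23 kg.
#'
#' Reference levels are CON, gestation group 1 and female throughout the
#' package.
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame` with columns `sample_id`, `treatment`,
#'   `gestation_group`, `fetal_sex` (factors) and `initial_bw_kg`.
#' @examples
#' d <- simulate_design(sim_config(n_per_treatment = 3, seed = 1))
#' table(d$treatment)
#' @export
simulate_design <- function(config) {
  if (!inherits(config, "sim_config"))
    config_error("config", "must be a sim_config object")
  n <- 2L * config$n_per_treatment
  with_seed(config$seed, {
    treatment <- factor(rep(c("CON", "PRU"), each = config$n_per_treatment),
                        levels = c("CON", "PRU"))
    gg_levels <- as.character(seq_len(config$n_gestation_groups))
    fs_levels <- if (config$fetal_sex_levels == 2) c("F", "M") else
      paste0("S", seq_len(config$fetal_sex_levels))
    draw_balanced <- function(levels, size) {
      # as-balanced-as-possible assignment, order shuffled by the seeded stream
      base <- rep_len(levels, size)
      sample(base, size)
    }
    gestation_group <- factor(unlist(lapply(1:2, function(i)
      draw_balanced(gg_levels, config$n_per_treatment))), levels = gg_levels)
    fetal_sex <- factor(unlist(lapply(1:2, function(i)
      draw_balanced(fs_levels, config$n_per_treatment))), levels = fs_levels)
    data.frame(
      sample_id = sprintf("S%02d", seq_len(n)),
      treatment = treatment,
      gestation_group = gestation_group,
      fetal_sex = fetal_sex,
      initial_bw_kg = round(stats::rnorm(n, 545, 23), 1),
      stringsAsFactors = FALSE
    )
  })
}

# Per-sample log-scale fixed-effect contribution for one protein (or the ZI
# linear predictor), in reference-level coding.
sample_linear_predictor <- function(design, intercept, eff_trt, eff_gg, eff_fs) {
  eta <- rep(intercept, nrow(design))
  eta <- eta + ifelse(design$treatment == levels(design$treatment)[1], 0, eff_trt)
  gg_idx <- as.integer(design$gestation_group)
  eta <- eta + c(0, eff_gg)[gg_idx]
  fs_idx <- as.integer(design$fetal_sex)
  eta <- eta + c(0, eff_fs)[fs_idx]
  eta
}

#' Simulate a protein-group abundance matrix
#'
#' Draws, for each protein and sample, a negative binomial count with mean
#' \eqn{LS_s \exp(\mu_p + T_i + GG_j + FS_k)} and size (overdispersion)
#' parameter `config$dispersion`, where \eqn{LS_s} is the sample's
#' library-size multiplier drawn log-uniformly over
#' `config$library_size_range`. Under a zero-inflated configuration each
#' observation is replaced by a structural zero with probability
#' \eqn{\pi_s = \mathrm{logit}^{-1}} of the configured ZI linear predictor.
#' Counts are drawn before the zero-inflation indicators, so a ZI
#' configuration with \eqn{\pi = 0} reproduces the non-ZI draw exactly.
#'
#' Each protein uses an independent random stream seeded by the protein index,
#' so enlarging `n_proteins` never perturbs earlier proteins.
#'
#' @param config A [sim_config()] object.
#' @param design A design sheet from [simulate_design()] (at least 2 rows).
#' @return An [abundance_set] whose `truth` element is a per-protein
#'   data.frame of generative parameters (baseline log-mean, treatment effect,
#'   QC flags) for recovery tests.
#' @export
simulate_abundance <- function(config, design) {
  if (!inherits(config, "sim_config"))
    config_error("config", "must be a sim_config object")
  if (!is.data.frame(design) || nrow(design) < 2)
    config_error("design", "must be a design data.frame with at least 2 rows")
  n_s <- nrow(design)
  n_p <- config$n_proteins

  zi_on <- config$zi_model != "none"
  zi_eta <- if (zi_on) {
    sample_linear_predictor(
      design, config$zi_intercept,
      if (config$zi_model %in% c("trt", "full")) config$zi_effect_treatment else 0,
      if (config$zi_model == "full") config$zi_effect_gestation else
        numeric(config$n_gestation_groups - 1),
      if (config$zi_model == "full") config$zi_effect_sex else
        numeric(config$fetal_sex_levels - 1))
  } else rep(-Inf, n_s)
  pi_s <- stats::plogis(zi_eta)

  beta_trt <- rep_len(config$effect_treatment, n_p)

  # sample-level and protein-level parameters from the base stream
  lib_size <- with_seed(config$seed, {
    exp(stats::runif(n_s, log(config$library_size_range[1]),
                     log(config$library_size_range[2])))
  })
  prot_pars <- with_seed(config$seed + 1L, {
    data.frame(
      protein_id = sprintf("PTN%05d", seq_len(n_p)),
      log_mean = stats::rnorm(n_p, config$baseline_log_mean, config$baseline_log_sd),
      effect_treatment = beta_trt,
      contaminant = stats::runif(n_p) < config$frac_contaminant,
      reverse = stats::runif(n_p) < config$frac_reverse,
      only_by_site = stats::runif(n_p) < config$frac_only_by_site,
      stringsAsFactors = FALSE
    )
  })

  counts <- matrix(0, n_p, n_s,
                   dimnames = list(prot_pars$protein_id, design$sample_id))
  for (p in seq_len(n_p)) {
    eta <- sample_linear_predictor(design, prot_pars$log_mean[p], beta_trt[p],
                                   config$effect_gestation, config$effect_sex)
    mu <- lib_size * exp(eta)
    counts[p, ] <- with_seed(protein_seed(config$seed, p), {
      y <- stats::rnbinom(n_s, size = config$dispersion, mu = mu)
      if (zi_on) {
        u <- stats::runif(n_s)
        y[u < pi_s] <- 0
      }
      y
    })
  }

  m <- abundance_set(counts, design,
                     flags = prot_pars[, c("contaminant", "reverse", "only_by_site")])
  m$truth <- prot_pars
  m
}

#' Simulate toy diet and digestibility data with known ground truth
#'
#' Generates a proximate diet composition closed to 1000 g/kg DM (non-fibrous
#' carbohydrates computed by difference), per-animal dry-matter intakes, and
#' fecal marker/component concentrations consistent with a known true
#' digestibility, so that the marker arithmetic in the nutrition module can be
#' checked by exact inversion (and, with noise, by Monte-Carlo recovery).
#'
#' Fecal concentrations derive from the indigestible NDF (iNDF) internal
#' marker with 100% assumed recovery: marker intake = DMI x diet iNDF
#' concentration, true fecal DM = DMI x (1 - DM digestibility), and the fecal
#' iNDF concentration is their ratio, optionally perturbed by multiplicative
#' log-normal noise of SD `noise_sd`.
#'
#' @param seed Integer seed.
#' @param n_animals Number of animals (>= 1).
#' @param noise_sd Log-scale SD of measurement noise on fecal concentrations
#'   (0 = noise off, exact inversion).
#' @param true_digestibility Named vector of true digestibility coefficients
#'   for `dm`, `cp`, `ee`, `ndfap`, `nfc`; defaults are typical of a corn
#'   silage based gestation diet.
#' @return A list with `diet` (composition, g/kg DM), `records` (per-animal
#'   intakes and fecal concentrations) and `truth` (the generative values).
#' @export
simulate_nutrition <- function(seed, n_animals,
                               noise_sd = 0,
                               true_digestibility = c(dm = 0.66, cp = 0.62,
                                                      ee = 0.81, ndfap = 0.60,
                                                      nfc = 0.78)) {
  if (length(n_animals) != 1 || n_animals < 1 || n_animals != round(n_animals))
    config_error("n_animals", "must be a single integer >= 1")
  need <- c("dm", "cp", "ee", "ndfap", "nfc")
  if (!all(need %in% names(true_digestibility)))
    config_error("true_digestibility",
                 paste("must name", paste(need, collapse = ", ")))
  d <- true_digestibility
  with_seed(seed, {
    cp <- round(stats::runif(1, 110, 130))
    ee <- round(stats::runif(1, 25, 40))
    ndfap <- round(stats::runif(1, 330, 400))
    ash <- round(stats::runif(1, 50, 70))
    diet <- data.frame(
      diet = "BASAL",
      dm = round(stats::runif(1, 450, 550)),
      cp = cp, ee = ee, ndfap = ndfap, ash = ash,
      nfc = compute_nfc(cp, ee, ndfap, ash)
    )
    diet_indf_conc <- stats::runif(1, 0.15, 0.25)  # g iNDF / g diet DM

    dmi <- stats::rnorm(n_animals, 5900, 300)      # g DM/day
    comp_frac <- c(cp = cp, ee = ee, ndfap = ndfap, nfc = diet$nfc) / 1000
    indf_intake <- dmi * diet_indf_conc
    fecal_dm_true <- dmi * (1 - d[["dm"]])
    noise <- function(n) exp(stats::rnorm(n, 0, noise_sd))
    fecal_indf_conc <- indf_intake / fecal_dm_true * noise(n_animals)

    records <- data.frame(
      animal_id = sprintf("A%03d", seq_len(n_animals)),
      intake_dm = dmi,
      intake_cp = dmi * comp_frac[["cp"]],
      intake_ee = dmi * comp_frac[["ee"]],
      intake_ndfap = dmi * comp_frac[["ndfap"]],
      intake_nfc = dmi * comp_frac[["nfc"]],
      diet_indf_conc = diet_indf_conc,
      indf_intake = indf_intake,
      fecal_indf_conc = fecal_indf_conc,
      stringsAsFactors = FALSE
    )
    for (comp in c("cp", "ee", "ndfap", "nfc")) {
      out_true <- records[[paste0("intake_", comp)]] * (1 - d[[comp]])
      records[[paste0("fecal_", comp, "_conc")]] <-
        out_true / fecal_dm_true * noise(n_animals)
    }
    list(diet = diet, records = records,
         truth = list(digestibility = d, diet_indf_conc = diet_indf_conc,
                      fecal_dm = fecal_dm_true))
  })
}
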