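test_that("likelihood equals naive term-by-term summation on random instances", {
  for (s in 1:30) {
    inst <- random_instance(s)
    expect_equal(
      zinb_loglik(inst$params, inst$y, inst$offset, inst$design, inst$spec),
      naive_zinb_loglik(inst$beta, inst$log_theta, inst$gamma,
                        inst$y, inst$offset, inst$X, inst$Z),
      tolerance = 1e-10)
  }
})

test_that("likelihood limits: vanishing zero-inflation and a sure zero", {
  inst <- random_instance(42)
  nb <- model_spec("NB")
  zb <- model_spec("ZINB_basic")
  mats_nb <- zinbdap:::design_matrices(inst$design, nb, warn = FALSE)
  par_nb <- c(inst$beta[seq_len(ncol(mats_nb$X))], inst$log_theta)
  ll_nb <- zinb_loglik(par_nb, inst$y, inst$offset, inst$design, nb)
  # gamma intercept -> -Inf limit: ZINB collapses onto NB
  ll_zi <- zinb_loglik(c(par_nb, -100), inst$y, inst$offset, inst$design, zb)
  expect_equal(ll_zi, ll_nb, tolerance = 1e-10)

  # single y = 0 with pi ~ 1: the observation is certain, loglik 0
  d1 <- inst$design[1, , drop = FALSE]
  ll1 <- zinb_loglik(c(0, 0, 40), 0, 0, d1, zb)
  expect_equal(ll1, 0, tolerance = 1e-10)

  expect_identical(zinb_loglik(c(NA, par_nb[-1]), inst$y, inst$offset,
                               inst$design, nb), -Inf)
})

test_that("analytic gradient matches central differences", {
  for (s in c(3, 17)) {
    inst <- random_instance(s, n = 12)
    g_a <- unname(zinbdap:::zinb_grad_mats(inst$params, inst$y, inst$offset,
                                           inst$X, inst$Z))
    g_n <- vapply(seq_along(inst$params), function(i) {
      h <- 1e-6
      up <- dn <- inst$params
      up[i] <- up[i] + h; dn[i] <- dn[i] - h
      (zinbdap:::zinb_loglik_mats(up, inst$y, inst$offset, inst$X, inst$Z) -
         zinbdap:::zinb_loglik_mats(dn, inst$y, inst$offset, inst$X, inst$Z)) /
        (2 * h)
    }, numeric(1))
    expect_equal(g_a, g_n, tolerance = 1e-5)
  }
})

test_that("fitting recovers generative parameters and honors the offset contract", {
  cfg <- sim_config(n_per_treatment = 100, n_proteins = 1,
                    library_size_range = c(1e4, 1e4), baseline_log_mean = -5,
                    dispersion = 5, effect_treatment = 0.8, seed = 21)
  d <- simulate_design(cfg)
  m <- simulate_abundance(cfg, d)
  off <- rep(log(1e4), nrow(d))
  fit <- fit_model(m$counts[1, ], off, d, model_spec("NB"))
  expect_true(fit$converged)
  fc <- treatment_lnfc(fit)
  expect_lt(abs(fc$ln_fc - 0.8), 3 * fc$se)

  # doubling every normalized library size shifts only the intercept, by -ln 2
  fit2 <- fit_model(m$counts[1, ], off + log(2), d, model_spec("NB"))
  expect_equal(fit2$beta[["(Intercept)"]], fit$beta[["(Intercept)"]] - log(2),
               tolerance = 1e-4)
  expect_equal(fit2$beta[-1], fit$beta[-1], tolerance = 1e-4)
})

test_that("degenerate inputs are handled: constant response, dropped factors", {
  d <- make_design(6)
  y <- rep(25, 12)
  expect_true(suppressWarnings(fit_model(y, rep(0, 12), d, model_spec("NB")))$converged)
  fit <- suppressWarnings(fit_model(y, rep(0, 12), d, model_spec("NB")))
  expect_lt(abs(fit$beta[["treatmentPRU"]]), 1e-4)

  d1 <- d; d1$fetal_sex <- factor(rep("F", 12))
  expect_warning(fit_model(rpois(12, 20), rep(0, 12), d1, model_spec("NB")),
                 "fetal_sex")
})

test_that("a zero-inflated truth gives the nested model a strictly higher optimum", {
  cfg <- sim_config(n_per_treatment = 100, n_proteins = 1,
                    library_size_range = c(1e4, 1e4), baseline_log_mean = -5,
                    dispersion = 5, zi_model = "trt", zi_intercept = -1.5,
                    zi_effect_treatment = 2, seed = 31)
  d <- simulate_design(cfg)
  m <- simulate_abundance(cfg, d)
  off <- rep(log(1e4), nrow(d))
  y <- m$counts[1, ]
  f_nb <- suppressWarnings(fit_model(y, off, d, model_spec("NB")))
  f_trt <- suppressWarnings(fit_model(y, off, d, model_spec("ZINB_TRT")))
  expect_true(f_nb$converged && f_trt$converged)
  expect_gt(f_trt$loglik, f_nb$loglik)
})

test_that("fits agree with an independent ZINB implementation", {
  skip_if_not_installed("glmmTMB")
  cfg <- sim_config(n_per_treatment = 60, n_proteins = 1,
                    library_size_range = c(2e4, 2e4), baseline_log_mean = -5,
                    dispersion = 4, effect_treatment = 0.5, zi_model = "trt",
                    zi_intercept = -1, zi_effect_treatment = 1.2, seed = 41)
  d <- simulate_design(cfg)
  m <- simulate_abundance(cfg, d)
  off <- rep(log(2e4), nrow(d))
  y <- m$counts[1, ]
  ours <- fit_model(y, off, d, model_spec("ZINB_TRT"))
  dd <- d; dd$off <- off; dd$y <- y
  ref <- glmmTMB::glmmTMB(
    y ~ treatment + gestation_group + fetal_sex + offset(off),
    ziformula = ~treatment, family = glmmTMB::nbinom2, data = dd)
  expect_equal(ours$loglik, as.numeric(logLik(ref)), tolerance = 1e-5)
  expect_equal(unname(ours$beta["treatmentPRU"]),
               unname(glmmTMB::fixef(ref)$cond["treatmentPRU"]),
               tolerance = 1e-3)
  expect_equal(unname(ours$gamma["zi_treatmentPRU"]),
               unname(glmmTMB::fixef(ref)$zi["treatmentPRU"]),
               tolerance = 1e-2)
})

test_that("treatment ln(FC) reporting is symmetric at zero and guards convergence", {
  f0 <- fake_fit("NB", loglik = -50, beta_trt = 0, se = 0.2)
  fc <- treatment_lnfc(f0)
  expect_equal(fc$ln_fc, 0)
  expect_equal(fc$ci95[["lower"]], -fc$ci95[["upper"]])
  expect_equal(fc$ci95[["upper"]], 1.96 * fc$se)

  bad <- fake_fit("NB", loglik = -50, converged = FALSE)
  expect_error(treatment_lnfc(bad), "converge")
})
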