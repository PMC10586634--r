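test_that("likelihood ratio test matches the chi-square closed form", {
  nb <- fake_fit("NB", loglik = -100)
  zb <- fake_fit("ZINB_basic", loglik = -100)
  out <- lrt(nb, zb)
  expect_equal(out$statistic, 0)
  expect_equal(out$df, 1)
  expect_equal(out$p, 1)

  zb2 <- fake_fit("ZINB_basic", loglik = -100 + 3.841 / 2)
  expect_equal(lrt(nb, zb2)$p, 0.05, tolerance = 1e-3)

  # floored at zero when the larger model lands lower numerically
  zb3 <- fake_fit("ZINB_basic", loglik = -100.001)
  expect_equal(lrt(nb, zb3)$statistic, 0)

  expect_error(lrt(zb, nb), "nested")
  expect_error(lrt(fake_fit("NB", -100, converged = FALSE), zb), "converged")
})

test_that("the cascade advances only on significant LRTs and short-circuits", {
  nb <- fake_fit("NB", loglik = -100)

  # all entry tests non-significant: NB retained
  sel <- select_model(list(NB = nb,
                           ZINB_basic = fake_fit("ZINB_basic", -99.9),
                           ZINB_TRT = fake_fit("ZINB_TRT", -99.8),
                           ZINB_full = fake_fit("ZINB_full", -99.7)))
  expect_equal(sel$selected_model, "NB")
  expect_length(sel$lrt_chain, 1)

  # p-chain (0.001, 0.20): ZINB_basic selected, ZINB_full never evaluated
  zb <- fake_fit("ZINB_basic", -100 + qchisq(0.999, 1) / 2)
  ztrt <- fake_fit("ZINB_TRT", zb$loglik + qchisq(0.80, 1) / 2)
  sel2 <- select_model(list(NB = nb, ZINB_basic = zb, ZINB_TRT = ztrt))
  expect_equal(sel2$selected_model, "ZINB_basic")
  expect_equal(unname(vapply(sel2$lrt_chain, `[[`, 0, "p")),
               c(0.001, 0.20), tolerance = 1e-6)

  # significant all the way down reaches ZINB_full
  zfull <- fake_fit("ZINB_full", ztrt$loglik + qchisq(0.999, 3) / 2)
  ztrt2 <- fake_fit("ZINB_TRT", zb$loglik + qchisq(0.999, 1) / 2)
  zfull2 <- fake_fit("ZINB_full", ztrt2$loglik + qchisq(0.999, 3) / 2)
  sel3 <- select_model(list(NB = nb, ZINB_basic = zb, ZINB_TRT = ztrt2,
                            ZINB_full = zfull2))
  expect_equal(sel3$selected_model, "ZINB_full")

  # non-converged candidate stops the cascade with a recorded status
  sel4 <- select_model(list(NB = nb, ZINB_basic = fake_fit("ZINB_basic", -90,
                                                           converged = FALSE)))
  expect_equal(sel4$selected_model, "NB")
  expect_match(sel4$lrt_chain[[1]]$status, "skipped")

  # same fits, same selection
  expect_identical(sel2$selected_model,
                   select_model(list(NB = nb, ZINB_basic = zb,
                                     ZINB_TRT = ztrt))$selected_model)
})

test_that("a strong zero-inflation treatment effect drives selection beyond ZINB_basic", {
  cfg <- sim_config(n_per_treatment = 48, n_proteins = 40,
                    library_size_range = c(2e4, 2e4), baseline_log_mean = -5,
                    dispersion = 5, zi_model = "trt", zi_intercept = -1,
                    zi_effect_treatment = 2, seed = 13)
  d <- simulate_design(cfg)
  m <- simulate_abundance(cfg, d)
  off <- rep(log(2e4), nrow(d))
  specs <- lapply(c("NB", "ZINB_basic", "ZINB_TRT", "ZINB_full"), model_spec)
  names(specs) <- c("NB", "ZINB_basic", "ZINB_TRT", "ZINB_full")
  picks <- vapply(seq_len(40), function(i) {
    fits <- lapply(specs, function(sp)
      suppressWarnings(fit_model(m$counts[i, ], off, d, sp)))
    tryCatch(select_model(fits)$selected_model, error = function(e) NA_character_)
  }, character(1))
  expect_gt(mean(picks %in% c("ZINB_TRT", "ZINB_full"), na.rm = TRUE), 0.5)
})

test_that("q-values reduce to Benjamini-Hochberg at pi0 = 1 and stay monotone", {
  set.seed(5)
  p <- c(runif(200), runif(20)^4, 0.2, 0.2)  # include ties and small values
  expect_equal(as.numeric(qvalues(p, pi0 = 1)), p.adjust(p, "BH"))

  expect_equal(as.numeric(qvalues(0.37, pi0 = 1)), 0.37)
  expect_identical(qvalues(numeric(0)), numeric(0))

  q <- as.numeric(qvalues(p))
  expect_true(all(q >= 0 & q <= 1))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))

  # NA p-values propagate without disturbing the rest
  pna <- c(p[1:10], NA)
  qna <- qvalues(pna, pi0 = 1)
  expect_true(is.na(qna[11]))
  expect_equal(as.numeric(qna[1:10]), p.adjust(p[1:10], "BH"))

  expect_error(qvalues(c(0.5, 1.2)), "0, 1")
})

test_that("uniform null p-values yield no discoveries in the vast majority of seeds", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    sum(qvalues(runif(2000)) < 0.05)
  }, numeric(1))
  expect_gte(sum(hits == 0), 8)
})

test_that("exclusive proteins require detection in one group only", {
  counts <- rbind(
    pru_only = c(rep(0, 4), 5, 7, 9, 0),
    both     = c(1, 0, 0, 0, 2, 0, 0, 0),
    con_only = c(3, 2, 0, 0, rep(0, 4)),
    neither  = rep(0, 8))
  d <- make_design(4)[1:8, ]
  colnames(counts) <- d$sample_id
  m <- abundance_set(counts, d)
  ex <- exclusive_proteins(m)
  expect_equal(ex$exclusive_to$PRU, "pru_only")
  expect_equal(ex$exclusive_to$CON, "con_only")
  expect_false("both" %in% unlist(ex$exclusive_to))
  expect_false("neither" %in% unlist(ex$exclusive_to))

  d_one <- d; d_one$treatment <- factor(rep("CON", 8), levels = c("CON", "PRU"))
  m_one <- abundance_set(counts, d_one)
  expect_error(exclusive_proteins(m_one), "treatment group")
})

test_that("the pipeline report is internally consistent on a small dataset", {
  cfg <- sim_config(n_per_treatment = 8, n_proteins = 60,
                    baseline_log_mean = -5.5, dispersion = 20,
                    effect_treatment = c(rep(1, 6), rep(0, 54)),
                    frac_contaminant = 0.05, seed = 17)
  d <- simulate_design(cfg)
  m <- simulate_abundance(cfg, d)
  res <- run_dap_pipeline(m)
  r <- res$report
  expect_equal(r$flag_filter$retained,
               60 - sum(with(m$truth, contaminant | reverse | only_by_site)))
  expect_equal(nrow(res$results) + length(r$excluded_nonconverged),
               r$protein_filter$retained)
  expect_equal(r$n_dap, sum(res$results$is_dap))
  expect_true(r$exclusive_on_same_matrix)
  expect_true(all(diff(res$results$treatment_q) >= -1e-12))
  # the strong planted effects dominate the DAP calls
  if (r$n_dap > 0)
    expect_true(all(as.integer(sub("PTN", "", res$results$protein_id[res$results$is_dap])) <= 6))
})
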