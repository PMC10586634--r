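make_set <- function(counts, n_per_trt = ncol(counts) / 2, flags = NULL) {
  d <- make_design(ceiling(ncol(counts) / 2))[seq_len(ncol(counts)), ]
  d$treatment <- droplevels(d$treatment)
  colnames(counts) <- d$sample_id
  abundance_set(counts, d, flags)
}

test_that("flag filtering removes exactly the flagged proteins", {
  set.seed(1)
  counts <- matrix(rpois(5 * 4, 20), 5, 4)
  flags <- data.frame(contaminant = c(TRUE, FALSE, FALSE, FALSE, FALSE),
                      reverse = c(FALSE, TRUE, FALSE, FALSE, FALSE),
                      only_by_site = rep(FALSE, 5))
  m <- make_set(counts, flags = flags)
  f <- filter_flagged_proteins(m)
  expect_equal(nrow(f$counts), 3)
  expect_equal(f$log$flag_filter$removed, 2)

  # no flags set: identity on the data
  m0 <- make_set(counts)
  expect_identical(filter_flagged_proteins(m0)$counts, m0$counts)

  # generator truth: retained count equals total minus truth-table flags
  cfg <- sim_config(n_per_treatment = 4, n_proteins = 1000,
                    frac_contaminant = 0.1, frac_reverse = 0.02,
                    frac_only_by_site = 0.02, seed = 11)
  sim <- simulate_abundance(cfg, simulate_design(cfg))
  truth_flagged <- with(sim$truth, sum(contaminant | reverse | only_by_site))
  expect_equal(nrow(filter_flagged_proteins(sim)$counts), 1000 - truth_flagged)

  broken <- m
  broken$flags$only_by_site <- NULL
  expect_error(filter_flagged_proteins(broken), "only_by_site")
})

test_that("sample sparsity filter drops near-empty samples and is idempotent", {
  set.seed(2)
  counts <- matrix(rpois(200 * 24, 10) + 1, 200, 24)
  counts[, 5] <- 0
  m <- make_set(counts)
  f <- filter_sparse_samples(m)
  expect_equal(ncol(f$counts), 23)
  expect_equal(f$log$sample_filter$removed_ids, "S05")
  expect_equal(f$samples$lib.size, unname(colSums(f$counts)))

  # identity when all samples detect enough, idempotence in general
  full <- make_set(matrix(rpois(50 * 6, 10) + 1, 50, 6))
  expect_identical(filter_sparse_samples(full)$counts, full$counts)
  expect_identical(filter_sparse_samples(f)$counts, f$counts)

  expect_error(filter_sparse_samples(make_set(matrix(0, 200, 4))),
               "every sample")
})

test_that("protein sparsity filter implements the 2-or-fewer-of-22 rule", {
  counts <- matrix(50, 4, 22)
  counts[1, ] <- c(rep(7, 2), rep(0, 20))   # detected in exactly 2 -> removed
  counts[2, ] <- c(rep(7, 3), rep(0, 19))   # detected in 3 -> kept
  counts[3, 1] <- 0
  m <- make_set(counts)
  f <- filter_sparse_proteins(m)
  expect_equal(rownames(f$counts), rownames(m$counts)[2:4])
  expect_equal(f$log$protein_filter$min_samples, 3)

  # identity when fully observed; idempotence
  expect_identical(filter_sparse_proteins(f)$counts, f$counts)
  expect_error(filter_sparse_proteins(make_set(matrix(0, 3, 22))),
               "every protein")
})

test_that("TMM factors are exact for identical columns and scale-invariant", {
  set.seed(3)
  counts <- matrix(rep(rpois(40, 50) + 1, 6), 40, 6)
  m <- tmm_normalize(make_set(counts))
  expect_equal(m$samples$norm.factors, rep(1, 6))

  base <- matrix(rnbinom(50 * 6, mu = 100, size = 5) + 1, 50, 6)
  f1 <- tmm_normalize(make_set(base))$samples$norm.factors
  f2 <- tmm_normalize(make_set(base * 7))$samples$norm.factors
  expect_equal(f1, f2, tolerance = 1e-12)
  expect_lt(abs(exp(mean(log(f1))) - 1), 1e-12)
})

test_that("TMM matches an independent loop-based re-derivation", {
  set.seed(4)
  counts <- matrix(rnbinom(50 * 6, mu = 80, size = 3), 50, 6)
  counts[counts == 0] <- 0   # keep zeros: excluded pairwise in M/A space
  m <- tmm_normalize(make_set(counts))
  expect_equal(m$samples$norm.factors, naive_tmm_factors(counts),
               tolerance = 1e-10)
  expect_equal(effective_lib_sizes(m),
               setNames(m$samples$lib.size * m$samples$norm.factors,
                        m$samples$sample_id))
})

test_that("a sample with no co-detected proteins triggers a named error", {
  counts <- matrix(0, 20, 3)
  counts[1:10, 1:2] <- 50
  counts[11:20, 3] <- 50
  m <- make_set(counts)
  expect_error(tmm_normalize(m), "shares no detected proteins")
})

test_that("protein-groups and design files round-trip through disk", {
  cfg <- sim_config(n_per_treatment = 3, n_proteins = 20,
                    frac_contaminant = 0.2, seed = 6)
  d <- simulate_design(cfg)
  m <- simulate_abundance(cfg, d)
  tsv <- tempfile(fileext = ".tsv"); csv <- tempfile(fileext = ".csv")
  write_protein_groups(m, tsv)
  write_design(d, csv)
  d2 <- read_design(csv)
  m2 <- read_protein_groups(tsv, d2)
  expect_equal(unname(m2$counts), unname(m$counts))
  expect_equal(m2$flags, m$flags, ignore_attr = TRUE)
  expect_equal(levels(d2$treatment), c("CON", "PRU"))
  unlink(c(tsv, csv))
})
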