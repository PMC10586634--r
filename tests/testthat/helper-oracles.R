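# Independent oracles, deliberately written as plain loops with direct
# formula evaluation so they share no code path with the package internals.

# NB pmf via gamma functions
naive_nb_pmf <- function(y, mu, theta) {
  exp(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
        theta * (log(theta) - log(theta + mu)) +
        y * (log(mu) - log(theta + mu)))
}

# term-by-term ZINB log-likelihood; X/Z are design matrices (Z with 0 columns
# for the plain NB family)
naive_zinb_loglik <- function(beta, log_theta, gamma, y, offset, X, Z) {
  theta <- exp(min(log_theta, 25))
  ll <- 0
  for (s in seq_along(y)) {
    mu <- exp(offset[s] + sum(X[s, ] * beta))
    pmf <- naive_nb_pmf(y[s], mu, theta)
    if (ncol(Z) > 0) {
      pi_s <- 1 / (1 + exp(-sum(Z[s, ] * gamma)))
      dens <- if (y[s] == 0) pi_s + (1 - pi_s) * pmf else (1 - pi_s) * pmf
    } else {
      dens <- pmf
    }
    ll <- ll + log(dens)
  }
  ll
}

# step-by-step re-derivation of the TMM normalization factors (trimmed mean
# of M-values, precision-weighted, double-trimmed, geometric mean rescaled)
naive_tmm_factors <- function(counts, lib = colSums(counts),
                              trim_m = 0.30, trim_a = 0.05, ref = NULL) {
  ns <- ncol(counts)
  if (is.null(ref)) {
    uq <- numeric(ns)
    for (j in seq_len(ns)) uq[j] <- quantile(counts[, j], 0.75) / lib[j]
    ref <- which.min(abs(uq - mean(uq)))
  }
  f <- numeric(ns)
  for (j in seq_len(ns)) {
    obs <- counts[, j]; refc <- counts[, ref]
    nO <- lib[j]; nR <- lib[ref]
    M <- A <- w <- numeric(0)
    for (p in seq_len(nrow(counts))) {
      m <- log2((obs[p] / nO) / (refc[p] / nR))
      a <- (log2(obs[p] / nO) + log2(refc[p] / nR)) / 2
      if (is.finite(m) && is.finite(a) && a > -1e10) {
        M <- c(M, m); A <- c(A, a)
        w <- c(w, (nO - obs[p]) / nO / obs[p] + (nR - refc[p]) / nR / refc[p])
      }
    }
    if (max(abs(M)) < 1e-6) { f[j] <- 1; next }
    n <- length(M)
    loL <- floor(n * trim_m) + 1; hiL <- n + 1 - loL
    loS <- floor(n * trim_a) + 1; hiS <- n + 1 - loS
    keep <- rank(M) >= loL & rank(M) <= hiL & rank(A) >= loS & rank(A) <= hiS
    f[j] <- 2^(sum(M[keep] / w[keep], na.rm = TRUE) /
                 sum(1 / w[keep], na.rm = TRUE))
  }
  f / exp(mean(log(f)))
}

# small balanced design without going through the simulator
make_design <- function(n_per_trt = 12, seed = 1) {
  n <- 2 * n_per_trt
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    data.frame(
      sample_id = sprintf("S%02d", 1:n),
      treatment = factor(rep(c("CON", "PRU"), each = n_per_trt),
                         levels = c("CON", "PRU")),
      gestation_group = factor(rep_len(rep(1:3, length.out = n_per_trt), n)),
      fetal_sex = factor(rep_len(c("F", "M"), n)),
      initial_bw_kg = rnorm(n, 545, 23),
      stringsAsFactors = FALSE
    )
  })
}

# one random small model instance for likelihood-oracle checks
random_instance <- function(seed, n = 8) {
  set.seed(seed)
  d <- make_design(max(4, ceiling(n / 2)), seed = seed)[seq_len(n), ]
  d$treatment <- droplevels(d$treatment)
  spec_name <- sample(c("NB", "ZINB_basic", "ZINB_TRT", "ZINB_full"), 1)
  spec <- model_spec(spec_name)
  mats <- zinbdap:::design_matrices(d, spec, warn = FALSE)
  beta <- rnorm(ncol(mats$X), 0, 0.5); beta[1] <- rnorm(1, 1, 0.5)
  gamma <- if (ncol(mats$Z)) rnorm(ncol(mats$Z), 0, 1) else numeric(0)
  log_theta <- log(runif(1, 0.5, 20))
  offset <- rnorm(n, 2, 0.3)
  y <- rnbinom(n, size = exp(log_theta),
               mu = exp(offset + drop(mats$X %*% beta)))
  if (ncol(mats$Z)) {
    pi_s <- plogis(drop(mats$Z %*% gamma))
    y[runif(n) < pi_s] <- 0
  }
  list(design = d, spec = spec, X = mats$X, Z = mats$Z, beta = beta,
       gamma = gamma, log_theta = log_theta, offset = offset, y = y,
       params = c(beta, log_theta, gamma))
}

# fabricate a converged fit object for cascade/LRT unit tests
fake_fit <- function(name, loglik, beta_trt = 0.2, se = 0.1, n_obs = 24,
                     converged = TRUE) {
  spec <- model_spec(name)
  n_beta <- 5L
  n_gamma <- c(NB = 0L, ZINB_basic = 1L, ZINB_TRT = 2L, ZINB_full = 5L)[[name]]
  beta <- stats::setNames(c(-1, beta_trt, 0, 0, 0),
                          c("(Intercept)", "treatmentPRU", "gestation_group2",
                            "gestation_group3", "fetal_sexM"))
  nms <- c(names(beta), if (n_gamma) paste0("zi_g", seq_len(n_gamma)))
  V <- diag(se^2, n_beta + n_gamma)
  dimnames(V) <- list(nms, nms)
  df <- n_obs - n_beta - n_gamma
  # undo the small-sample SE correction so the fabricated Wald SE equals `se`
  V["treatmentPRU", "treatmentPRU"] <- se^2 * df / n_obs
  structure(list(spec = spec, beta = beta,
                 gamma = stats::setNames(numeric(n_gamma),
                                         if (n_gamma) paste0("zi_g", seq_len(n_gamma))),
                 dispersion = 10, loglik = loglik,
                 n_params = n_beta + n_gamma + 1L,
                 converged = converged, vcov = V,
                 n_obs = n_obs, df_resid = max(df, 1L)),
            class = "zinb_fit")
}
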