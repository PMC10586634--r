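# Per-protein count models: negative binomial with log link and
# normalized-library-size offset, plus three zero-inflated variants whose
# logit-scale zero probability depends on nothing (intercept), on treatment,
# or on treatment + gestation group + fetal sex. The count part is identical
# across all four models.

# dispersion is optimized on the log scale; beyond this cap the likelihood is
# numerically Poisson and is treated as flat
LOGTHETA_MAX <- 25

#' Specify one of the four per-protein count models
#'
#' The count (non-zero-inflated) linear predictor is always
#' intercept + treatment + gestation group + fetal sex. The four models
#' differ only in the zero-inflation part: `NB` has none, `ZINB_basic` an
#' intercept only, `ZINB_TRT` adds treatment, and `ZINB_full` uses all four
#' terms.
#'
#' @param name One of `"NB"`, `"ZINB_basic"`, `"ZINB_TRT"`, `"ZINB_full"`.
#' @return A `"model_spec"` object.
#' @export
model_spec <- function(name = c("NB", "ZINB_basic", "ZINB_TRT", "ZINB_full")) {
  name <- match.arg(name)
  zi_terms <- switch(name,
    NB = character(0),
    ZINB_basic = "intercept",
    ZINB_TRT = c("intercept", "treatment"),
    ZINB_full = c("intercept", "treatment", "gestation_group", "fetal_sex"))
  structure(list(name = name,
                 family = if (name == "NB") "NB" else "ZINB",
                 count_terms = c("intercept", "treatment", "gestation_group",
                                 "fetal_sex"),
                 zi_terms = zi_terms),
            class = "model_spec")
}

# ranked nesting order of the four specs
model_order <- c(NB = 1, ZINB_basic = 2, ZINB_TRT = 3, ZINB_full = 4)

# Build the count (X) and zero-inflation (Z) design matrices for a spec.
# Factors reduced to a single level after QC are dropped with a warning.
design_matrices <- function(design, spec, warn = TRUE) {
  vars <- c("treatment", "gestation_group", "fetal_sex")
  d <- design
  usable <- character(0)
  dropped <- character(0)
  for (v in vars) {
    if (is.null(d[[v]])) { dropped <- c(dropped, v); next }
    d[[v]] <- droplevels(as.factor(d[[v]]))
    if (nlevels(d[[v]]) >= 2) usable <- c(usable, v) else dropped <- c(dropped, v)
  }
  if (length(dropped) && warn)
    warning("dropping degenerate design factor(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  form <- if (length(usable))
    stats::as.formula(paste("~", paste(usable, collapse = " + "))) else ~1
  X <- stats::model.matrix(form, d)
  zi_vars <- intersect(setdiff(spec$zi_terms, "intercept"), usable)
  zform <- if (length(zi_vars))
    stats::as.formula(paste("~", paste(zi_vars, collapse = " + "))) else ~1
  Z <- if (spec$family == "ZINB") stats::model.matrix(zform, d) else
    matrix(numeric(0), nrow(d), 0)
  list(X = X, Z = Z)
}

split_params <- function(params, X, Z) {
  p <- ncol(X); q <- ncol(Z)
  list(beta = params[seq_len(p)],
       log_theta = params[p + 1],
       gamma = if (q) params[p + 1 + seq_len(q)] else numeric(0))
}

#' Zero-inflated negative binomial log-likelihood
#'
#' Evaluates the joint log-likelihood of a per-protein abundance vector under
#' one of the four model specifications. For the ZINB family,
#' \eqn{f(0) = \pi_s + (1-\pi_s)\,\mathrm{NB}(0)} and
#' \eqn{f(y>0) = (1-\pi_s)\,\mathrm{NB}(y)} with
#' \eqn{\pi_s = \mathrm{logit}^{-1}(z_s^\top\gamma)}; for the NB family
#' \eqn{\pi \equiv 0}. The NB mean is \eqn{\exp(\mathrm{offset}_s +
#' x_s^\top\beta)} so the offset (log normalized library size) enters the
#' model multiplicatively.
#'
#' @param params Parameter vector `c(beta, log_theta, gamma)` where `beta`
#'   matches the count design matrix columns, `log_theta` is the log NB size,
#'   and `gamma` (ZINB only) matches the zero-inflation design columns.
#' @param y Nonnegative abundance vector.
#' @param offset Log normalized library sizes (finite, one per sample).
#' @param design Sample design `data.frame`.
#' @param spec A [model_spec()].
#' @return The scalar log-likelihood; `-Inf` for non-finite parameters
#'   (optimizer-safe).
#' @export
zinb_loglik <- function(params, y, offset, design, spec) {
  mats <- design_matrices(design, spec, warn = FALSE)
  zinb_loglik_mats(params, y, offset, mats$X, mats$Z)
}

zinb_loglik_mats <- function(params, y, offset, X, Z) {
  if (any(!is.finite(params))) return(-Inf)
  pr <- split_params(params, X, Z)
  theta <- exp(min(pr$log_theta, LOGTHETA_MAX))
  mu <- exp(offset + drop(X %*% pr$beta))
  ll_nb <- stats::dnbinom(y, size = theta, mu = mu, log = TRUE)
  if (ncol(Z) == 0) {
    val <- sum(ll_nb)
  } else {
    zeta <- drop(Z %*% pr$gamma)
    lp1 <- stats::plogis(zeta, log.p = TRUE)    # log pi
    lp0 <- stats::plogis(-zeta, log.p = TRUE)   # log(1 - pi)
    iszero <- y == 0
    ll <- lp0 + ll_nb
    if (any(iszero)) {
      a <- lp1[iszero]
      b <- ll[iszero]
      mx <- pmax(a, b)
      lz <- mx + log(exp(a - mx) + exp(b - mx))
      lz[!is.finite(mx)] <- -Inf
      ll[iszero] <- lz
    }
    val <- sum(ll)
  }
  if (is.nan(val)) -Inf else val
}

# analytic gradient of zinb_loglik_mats; zero for a capped dispersion
zinb_grad_mats <- function(params, y, offset, X, Z) {
  pr <- split_params(params, X, Z)
  capped <- pr$log_theta >= LOGTHETA_MAX
  theta <- exp(min(pr$log_theta, LOGTHETA_MAX))
  mu <- exp(offset + drop(X %*% pr$beta))
  n <- length(y)

  # per-observation NB score pieces
  d_beta_nb <- (y - mu) * theta / (theta + mu)          # x weight, y observed
  d_th_nb <- theta * (digamma(y + theta) - digamma(theta) +
                      log(theta / (theta + mu)) + 1 - (y + theta) / (theta + mu))
  if (ncol(Z) == 0) {
    g <- c(drop(crossprod(X, d_beta_nb)), if (capped) 0 else sum(d_th_nb))
    return(g)
  }
  zeta <- drop(Z %*% pr$gamma)
  pi_s <- stats::plogis(zeta)
  iszero <- y == 0
  lp0 <- stats::plogis(-zeta, log.p = TRUE)
  p0 <- exp(theta * (log(theta) - log(theta + mu)))     # NB mass at zero
  S <- pi_s + (1 - pi_s) * p0

  wb <- d_beta_nb                                        # beta weights
  wt <- d_th_nb                                          # log-theta weights
  wg <- -pi_s                                            # gamma weights (y>0)
  if (any(iszero)) {
    i <- iszero
    Si <- S[i]
    wb[i] <- -(1 - pi_s[i]) * p0[i] * theta * mu[i] / (theta + mu[i]) / Si
    wt[i] <- (1 - pi_s[i]) * p0[i] * theta *
      (log(theta / (theta + mu[i])) + mu[i] / (theta + mu[i])) / Si
    wg[i] <- pi_s[i] * (1 - pi_s[i]) * (1 - p0[i]) / Si
  }
  c(drop(crossprod(X, wb)),
    if (capped) 0 else sum(wt),
    drop(crossprod(Z, wg)))
}

init_params <- function(y, offset, X, Z) {
  pos <- y > 0
  beta0 <- numeric(ncol(X))
  if (sum(pos) >= 1) {
    fit <- stats::lm.fit(X[pos, , drop = FALSE], log(y[pos]) - offset[pos])
    b <- fit$coefficients
    b[!is.finite(b)] <- 0
    beta0 <- b
  } else {
    beta0[1] <- log(0.5) - mean(offset)
  }
  r <- y / exp(offset)
  mu_r <- mean(r)
  v_r <- stats::var(r)
  theta0 <- if (is.finite(v_r) && v_r > mu_r && mu_r > 0)
    mu_r^2 / (v_r - mu_r) else 50
  theta0 <- min(max(theta0, 0.05), 1e4)
  par <- c(beta0, log(theta0))
  if (ncol(Z)) {
    mu_hat <- exp(offset + drop(X %*% beta0))
    p0 <- mean(exp(theta0 * (log(theta0) - log(theta0 + mu_hat))))
    excess <- max(mean(y == 0) - p0, 0.01)
    gamma0 <- c(stats::qlogis(min(excess, 0.95)), numeric(ncol(Z) - 1))
    par <- c(par, gamma0)
  }
  par
}

#' Fit a count model to one protein by maximum likelihood
#'
#' Maximizes [zinb_loglik()] by BFGS with analytic gradients, falling back to
#' Nelder-Mead when the quasi-Newton path fails. A fit is reported as
#' non-converged (never an error) when the optimizer does not meet tolerance
#' or the observed-information matrix for the regression coefficients is not
#' positive definite; downstream model selection only considers converged
#' fits. A design factor left with a single level after QC is dropped with a
#' warning.
#'
#' @param y Nonnegative abundance vector (one protein across samples).
#' @param offset Log normalized library sizes.
#' @param design Sample design `data.frame` (`treatment`, `gestation_group`,
#'   `fetal_sex`).
#' @param spec A [model_spec()].
#' @param init Optional starting parameter vector `c(beta, log_theta,
#'   gamma)`; defaults to a log-linear moment fit on positive observations,
#'   method-of-moments dispersion, and a zero-excess logit intercept.
#' @return A `"zinb_fit"` object: `beta`, `gamma`, `dispersion` (NB size),
#'   `loglik`, `n_params`, `converged`, and `vcov` for `(beta, gamma)`.
#' @export
fit_model <- function(y, offset, design, spec, init = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (length(offset) == 1) offset <- rep(offset, length(y))
  if (length(y) != length(offset) || length(y) != nrow(design))
    stop("y, offset and design dimensions disagree")
  if (any(y < 0) || any(!is.finite(offset)))
    stop("y must be nonnegative and offset finite")
  mats <- design_matrices(design, spec)
  X <- mats$X; Z <- mats$Z
  par0 <- init %||% init_params(y, offset, X, Z)

  negll <- function(p) -zinb_loglik_mats(p, y, offset, X, Z)
  neggr <- function(p) -zinb_grad_mats(p, y, offset, X, Z)

  opt <- tryCatch(
    stats::optim(par0, negll, neggr, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) NULL)
  if (is.null(opt) || opt$convergence != 0 || !is.finite(opt$value)) {
    start <- if (!is.null(opt) && is.finite(opt$value)) opt$par else par0
    opt2 <- tryCatch(
      stats::optim(start, negll, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(opt2) && (is.null(opt) || opt2$value <= opt$value)) opt <- opt2
  }

  p_names <- c(colnames(X), "log_theta",
               if (ncol(Z)) paste0("zi_", colnames(Z)))
  n_params <- ncol(X) + ncol(Z) + 1L
  fail <- function() {
    structure(list(spec = spec,
                   beta = stats::setNames(rep(NA_real_, ncol(X)), colnames(X)),
                   gamma = stats::setNames(rep(NA_real_, ncol(Z)),
                                           if (ncol(Z)) paste0("zi_", colnames(Z))),
                   dispersion = NA_real_, loglik = -Inf,
                   n_params = n_params, converged = FALSE, vcov = NULL,
                   design_cols = list(X = colnames(X), Z = colnames(Z))),
              class = "zinb_fit")
  }
  if (is.null(opt) || !is.finite(opt$value)) return(fail())

  par <- stats::setNames(opt$par, p_names)
  pr <- split_params(par, X, Z)
  loglik <- -opt$value

  # observed information; vcov for the regression coefficients. When the
  # dispersion sits at its (numerically Poisson) cap its row is excluded so
  # equidispersed data still yield a usable fit.
  H <- tryCatch(stats::optimHess(opt$par, negll, neggr), error = function(e) NULL)
  vcov <- NULL
  converged <- opt$convergence == 0
  coef_idx <- c(seq_len(ncol(X)), if (ncol(Z)) ncol(X) + 1 + seq_len(ncol(Z)))
  if (!is.null(H) && all(is.finite(H))) {
    V <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
    if (is.null(V)) {
      Hc <- H[coef_idx, coef_idx, drop = FALSE]
      Vc <- tryCatch(chol2inv(chol(Hc)), error = function(e) NULL)
      if (!is.null(Vc)) {
        V <- matrix(NA_real_, length(par), length(par))
        V[coef_idx, coef_idx] <- Vc
      }
    }
    if (!is.null(V)) {
      dimnames(V) <- list(p_names, p_names)
      vcov <- V[coef_idx, coef_idx, drop = FALSE]
      if (any(diag(vcov) <= 0, na.rm = TRUE)) converged <- FALSE
    } else converged <- FALSE
  } else converged <- FALSE

  structure(list(spec = spec,
                 beta = stats::setNames(pr$beta, colnames(X)),
                 gamma = stats::setNames(pr$gamma,
                                         if (ncol(Z)) paste0("zi_", colnames(Z))),
                 dispersion = exp(min(pr$log_theta, LOGTHETA_MAX)),
                 loglik = loglik, n_params = n_params,
                 converged = converged, vcov = vcov,
                 n_obs = length(y),
                 df_resid = max(length(y) - ncol(X) - ncol(Z), 1L),
                 design_cols = list(X = colnames(X), Z = colnames(Z))),
            class = "zinb_fit")
}

# ML variance estimates ignore the estimated mean parameters; the usual
# n/(n-p) degrees-of-freedom factor restores near-nominal small-sample
# calibration (the analogue of the t-tests reported by mixed-model software).
wald_se_correction <- function(fit) sqrt(fit$n_obs / fit$df_resid)

#' @export
print.zinb_fit <- function(x, ...) {
  cat(sprintf("%s fit: loglik = %.4f, dispersion = %.3g, converged = %s\n",
              x$spec$name, x$loglik, x$dispersion, x$converged))
  print(round(x$beta, 4))
  if (length(x$gamma)) print(round(x$gamma, 4))
  invisible(x)
}

#' Treatment natural-log fold change with 95% confidence interval
#'
#' Extracts the PRU-vs-CON coefficient from the count part of a converged
#' fit. On the natural-log scale a negative value means lower and a positive
#' value greater abundance in PRU relative to CON. The interval is the Wald
#' interval \eqn{\beta \pm 1.96\,\mathrm{SE}}, where the SE carries the
#' \eqn{\sqrt{n/(n-p)}} small-sample correction of the ML covariance.
#'
#' @param fit A converged `"zinb_fit"`.
#' @return A list with `ln_fc`, `se` and `ci95` (lower, upper).
#' @export
treatment_lnfc <- function(fit) {
  stopifnot(inherits(fit, "zinb_fit"))
  if (!fit$converged) stop("model fit did not converge")
  nm <- grep("^treatment", names(fit$beta), value = TRUE)
  if (!length(nm)) stop("treatment coefficient not present in the fit")
  b <- unname(fit$beta[nm[1]])
  se <- sqrt(fit$vcov[nm[1], nm[1]]) * wald_se_correction(fit)
  list(ln_fc = b, se = se,
       ci95 = c(lower = b - 1.96 * se, upper = b + 1.96 * se))
}

# two-sided Wald t-test on the count-part treatment coefficient, with the
# small-sample SE correction and residual degrees of freedom
treatment_wald <- function(fit) {
  nm <- grep("^treatment", names(fit$beta), value = TRUE)
  if (!length(nm) || is.null(fit$vcov))
    return(list(estimate = NA_real_, se = NA_real_, p = NA_real_))
  b <- unname(fit$beta[nm[1]])
  v <- fit$vcov[nm[1], nm[1]]
  if (!is.finite(v) || v <= 0)
    return(list(estimate = b, se = NA_real_, p = NA_real_))
  se <- sqrt(v) * wald_se_correction(fit)
  list(estimate = b, se = se,
       p = 2 * stats::pt(-abs(b / se), df = fit$df_resid))
}
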