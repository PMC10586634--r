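# Fixed-effects analysis of animal performance, blood and urine traits:
# y = mu + treatment + gestation group + fetal sex + b1 * initial BW + e,
# with e ~ N(0, I * sigma_e^2), an iterative studentized-residual outlier
# screen, and a retain-only-if-highly-significant rule for the initial
# body-weight covariate.

trait_formula <- function(trait, covariate = TRUE) {
  rhs <- c("treatment", "gestation_group", "fetal_sex",
           if (covariate) "initial_bw_kg")
  stats::as.formula(paste(sprintf("`%s`", trait), "~",
                          paste(rhs, collapse = " + ")))
}

check_trait_data <- function(data, trait) {
  need <- c("treatment", "gestation_group", "fetal_sex", "initial_bw_kg", trait)
  miss <- setdiff(need, names(data))
  if (length(miss))
    format_error(paste("missing column(s):", paste(miss, collapse = ", ")))
  data <- data[!is.na(data[[trait]]), , drop = FALSE]
  for (v in c("treatment", "gestation_group", "fetal_sex"))
    data[[v]] <- droplevels(as.factor(data[[v]]))
  bw <- data$initial_bw_kg
  if (any(bw < 300 | bw > 900))
    warning("initial body weight outside the plausible bovine range (300-900 kg)",
            call. = FALSE)
  data
}

#' Iterative studentized-residual outlier removal
#'
#' Fits the trait model, computes externally studentized (leave-one-out)
#' residuals, removes the single observation with the largest absolute
#' residual exceeding the threshold, refits, and repeats until no residual
#' exceeds the threshold. Ties are broken by input order. The final residuals
#' are summarized with a Shapiro-Wilk normality p-value, which is reported
#' (with a warning below 0.05) but never used to reject data automatically.
#'
#' @param data Per-animal trait table (columns `treatment`,
#'   `gestation_group`, `fetal_sex`, `initial_bw_kg`, `animal_id` and the
#'   trait).
#' @param trait Name of the trait column.
#' @param threshold Absolute studentized-residual cutoff (default 3).
#' @param max_frac Abort if more than this fraction of observations would be
#'   removed (default 0.2).
#' @param internal Use internally studentized residuals instead of the
#'   deletion (leave-one-out) form.
#' @return A list with `data` (cleaned), `removed` (animal IDs in removal
#'   order) and `shapiro_p`.
#' @export
remove_outliers <- function(data, trait, threshold = 3, max_frac = 0.2,
                            internal = FALSE) {
  data <- check_trait_data(data, trait)
  if (is.null(data$animal_id))
    data$animal_id <- sprintf("A%03d", seq_len(nrow(data)))
  n0 <- nrow(data)
  removed <- character(0)
  form <- trait_formula(trait)
  repeat {
    fit <- stats::lm(form, data = data)
    rs <- if (internal) stats::rstandard(fit) else stats::rstudent(fit)
    rs[!is.finite(rs)] <- 0
    worst <- which.max(abs(rs))   # first index wins on ties
    if (abs(rs[worst]) <= threshold) break
    removed <- c(removed, data$animal_id[worst])
    data <- data[-worst, , drop = FALSE]
    if (length(removed) > max_frac * n0)
      stop(sprintf(
        "outlier removal aborted: more than %.0f%% of observations (%d of %d) flagged",
        100 * max_frac, length(removed), n0))
  }
  res <- stats::residuals(stats::lm(form, data = data))
  shapiro_p <- if (diff(range(res)) < 1e-10) NA_real_ else
    stats::shapiro.test(res)$p.value
  if (!is.na(shapiro_p) && shapiro_p < 0.05)
    warning(sprintf("residuals still non-normal after outlier removal (Shapiro-Wilk p = %.3g)",
                    shapiro_p), call. = FALSE)
  list(data = data, removed = removed, shapiro_p = shapiro_p)
}

#' Fit the fixed-effects model for one animal trait
#'
#' Ordinary least squares with treatment, gestation group and fetal sex fixed
#' effects and the initial-body-weight covariate. The covariate is retained
#' only when highly significant (`p < covariate_alpha`, default 1e-5);
#' otherwise the model is refit without it. Least-squares means are computed
#' at balanced factor weights. The treatment p-value is the two-sided t-test
#' on the PRU-vs-CON contrast (for a two-level factor in this additive model
#' it coincides with the type-III test). Significance convention: effects at
#' p < 0.05, trends at 0.05 < p <= 0.10.
#'
#' @param data Per-animal trait table (see [remove_outliers()]).
#' @param trait Name of the trait column.
#' @param covariate_alpha Retention threshold for the initial-BW covariate.
#' @param outlier_removal Run [remove_outliers()] first (default `TRUE`).
#' @param threshold Studentized-residual cutoff passed on.
#' @return A list of class `"trait_fit"`: the `lm` fit, `coefficients`
#'   table, `lsmeans` (per-treatment mean and SE), `treatment_p`,
#'   `covariate_retained`, `covariate_p`, `outliers_removed`, `shapiro_p`
#'   and `sigma2`.
#' @export
fit_trait <- function(data, trait, covariate_alpha = 1e-5,
                      outlier_removal = TRUE, threshold = 3) {
  data <- check_trait_data(data, trait)
  shapiro_p <- NA_real_
  removed <- character(0)
  if (outlier_removal) {
    cl <- remove_outliers(data, trait, threshold = threshold)
    data <- cl$data
    removed <- cl$removed
    shapiro_p <- cl$shapiro_p
  }
  if (min(table(data$treatment)) < 2)
    stop("fewer than 2 animals per treatment after outlier removal")

  fit <- stats::lm(trait_formula(trait), data = data)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased term(s): ", paste(bad, collapse = ", "))
  }
  ct <- summary(fit)$coefficients
  cov_p <- ct["initial_bw_kg", "Pr(>|t|)"]
  covariate_retained <- is.finite(cov_p) && cov_p < covariate_alpha
  if (!covariate_retained)
    fit <- stats::lm(trait_formula(trait, covariate = FALSE), data = data)

  emm <- emmeans::emmeans(fit, "treatment")
  lsm <- as.data.frame(summary(emm))
  tp <- summary(fit)$coefficients
  trt_row <- grep("^treatment", rownames(tp))
  treatment_p <- tp[trt_row, "Pr(>|t|)"]

  structure(list(trait = trait, model = fit,
                 coefficients = summary(fit)$coefficients,
                 lsmeans = lsm[, c("treatment", "emmean", "SE")],
                 treatment_p = unname(treatment_p),
                 covariate_retained = covariate_retained,
                 covariate_p = unname(cov_p),
                 outliers_removed = removed,
                 shapiro_p = shapiro_p,
                 sigma2 = summary(fit)$sigma^2),
            class = "trait_fit")
}

#' @export
print.trait_fit <- function(x, ...) {
  cat(sprintf("Trait: %s  (treatment p = %.3g%s)\n", x$trait, x$treatment_p,
              if (x$covariate_retained) ", initial-BW covariate retained" else ""))
  print(x$lsmeans, row.names = FALSE)
  if (length(x$outliers_removed))
    cat("outliers removed:", paste(x$outliers_removed, collapse = ", "), "\n")
  invisible(x)
}
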