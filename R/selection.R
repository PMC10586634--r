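# Nested likelihood-ratio-test model selection, Storey q-values, DAP calling
# and exclusive (presence/absence) protein detection.

#' Likelihood ratio test between two nested count-model fits
#'
#' The statistic is `2 * (loglik_full - loglik_reduced)`, floored at zero,
#' referred to a chi-square with degrees of freedom equal to the parameter
#' difference. At the zero-inflation boundary this naive reference is
#' conservative; it is used deliberately because it is what standard
#' mixed-model software reports.
#'
#' @param fit_reduced,fit_full Converged `"zinb_fit"` objects with
#'   `fit_reduced$spec` nested in `fit_full$spec`.
#' @return A list with `statistic`, `df` and `p`.
#' @export
lrt <- function(fit_reduced, fit_full) {
  stopifnot(inherits(fit_reduced, "zinb_fit"), inherits(fit_full, "zinb_fit"))
  if (model_order[fit_reduced$spec$name] >= model_order[fit_full$spec$name])
    stop("specs are not nested (reduced must precede full in the cascade)")
  if (!fit_reduced$converged || !fit_full$converged)
    stop("both fits must have converged")
  stat <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  df <- fit_full$n_params - fit_reduced$n_params
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# The cascade walks NB -> ZINB_basic -> ZINB_TRT -> ZINB_full, advancing only
# while the entry LRT is significant; ZINB_full is only ever compared when
# ZINB_TRT displaced ZINB_basic. `get_fit(name)` returns a fit or NULL; this
# lets the pipeline fit lazily while select_model() works from a prebuilt map.
select_cascade <- function(get_fit, alpha = 0.05) {
  chain <- list()
  nb <- get_fit("NB")
  if (is.null(nb) || !nb$converged)
    stop(structure(class = c("zinbdap_no_nb_fit", "error", "condition"),
                   list(message = "NB fit unavailable or non-converged; protein excluded from testing",
                        call = NULL)))
  current <- nb
  path <- c("ZINB_basic", "ZINB_TRT", "ZINB_full")
  for (nm in path) {
    cand <- get_fit(nm)
    cmp <- paste(current$spec$name, "vs", nm)
    if (is.null(cand) || !cand$converged) {
      chain[[cmp]] <- list(comparison = cmp, statistic = NA_real_,
                           df = NA_integer_, p = NA_real_,
                           status = "skipped: candidate did not converge")
      break
    }
    test <- lrt(current, cand)
    chain[[cmp]] <- c(list(comparison = cmp), test, list(status = "tested"))
    if (test$p < alpha) current <- cand else break
  }
  wald <- treatment_wald(current)
  fc <- if (current$converged && is.finite(wald$se %||% NA_real_))
    treatment_lnfc(current) else list(ln_fc = wald$estimate, se = NA_real_,
                                      ci95 = c(lower = NA_real_, upper = NA_real_))
  list(selected_model = current$spec$name,
       lrt_chain = chain,
       treatment_p = wald$p,
       ln_fc = fc$ln_fc,
       ci95 = fc$ci95,
       se_finite = is.finite(wald$se %||% NA_real_),
       selected_fit = current)
}

#' Select the per-protein model by the nested LRT cascade
#'
#' Starting from the NB fit, each zero-inflation extension enters only if its
#' likelihood-ratio test against the currently selected model has
#' `p < alpha`; `ZINB_full` is only considered when `ZINB_TRT` displaced
#' `ZINB_basic`. Non-converged candidates stop the cascade (they are skipped
#' with a recorded status). The treatment p-value is the two-sided Wald test
#' on the count-part treatment coefficient of the selected model, and the
#' natural-log fold change and its 95% CI come from [treatment_lnfc()].
#'
#' @param fits Named list of `"zinb_fit"` objects (names `NB`, `ZINB_basic`,
#'   `ZINB_TRT`, `ZINB_full`; later entries may be absent if unreachable).
#' @param alpha Entry significance level of each LRT (default 0.05).
#' @return A list: `selected_model`, `lrt_chain`, `treatment_p`, `ln_fc`,
#'   `ci95` and the selected fit.
#' @export
select_model <- function(fits, alpha = 0.05) {
  select_cascade(function(nm) fits[[nm]], alpha = alpha)
}

#' Storey q-values
#'
#' Computes false-discovery-rate q-values with the proportion of true nulls
#' \eqn{\pi_0} estimated by the smoother method: \eqn{\hat\pi_0(\lambda) =
#' \#\{p > \lambda\}/(m(1-\lambda))} on a \eqn{\lambda} grid, smoothed by a
#' cubic spline and evaluated at the largest \eqn{\lambda}. With `pi0 = 1`
#' the result is exactly the Benjamini-Hochberg step-up adjustment. q-values
#' are monotone nondecreasing in p.
#'
#' @param pvals Vector of p-values in `[0, 1]` (`NA`s propagate).
#' @param pi0 Optional fixed \eqn{\pi_0}; default estimates it (falling back
#'   to 1 when the grid is too sparse to smooth).
#' @param lambda Grid for the smoother estimate.
#' @return q-values in the original order.
#' @export
qvalues <- function(pvals, pi0 = NULL, lambda = seq(0.05, 0.95, 0.05)) {
  if (!length(pvals)) return(numeric(0))
  ok <- !is.na(pvals)
  p <- pvals[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    lam <- lambda[lambda < max(p)]
    if (length(lam) < 4 || m < 20) {
      pi0 <- 1
    } else {
      pi0_lam <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
      sp <- tryCatch(stats::smooth.spline(lam, pi0_lam, df = 3),
                     error = function(e) NULL)
      pi0 <- if (is.null(sp)) min(pi0_lam[length(pi0_lam)], 1) else
        stats::predict(sp, x = max(lam))$y
      pi0 <- min(max(pi0, 1e-8), 1)
    }
  }
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[o] <- pmin(1, cummin(pi0 * (m / (m:1)) * p[o]))
  out <- rep(NA_real_, length(pvals))
  out[ok] <- q
  attr(out, "pi0") <- pi0
  out
}

#' Proteins detected exclusively in one treatment group
#'
#' A protein is exclusive to a group when it is detected (abundance > 0) in
#' at least one sample of that group and in no sample of any other group.
#' Such presence/absence contrasts complement the differential-abundance
#' testing, which can only address proteins quantified in both groups.
#'
#' @param m A QC-filtered [abundance_set].
#' @param design Optional design `data.frame` (defaults to `m$samples`); must
#'   contain `treatment` with at least two non-empty levels.
#' @return A list with `exclusive_to` (named list of protein-ID vectors per
#'   group) and `detection_rule`.
#' @export
exclusive_proteins <- function(m, design = NULL) {
  stopifnot(inherits(m, "abundance_set"))
  design <- design %||% m$samples
  if (is.null(design$treatment)) stop("design lacks a treatment column")
  grp <- droplevels(as.factor(design$treatment))
  if (nlevels(grp) < 2) stop("treatment group missing from the design")
  det <- sapply(levels(grp), function(g)
    rowSums(m$counts[, grp == g, drop = FALSE] > 0))
  sets <- lapply(levels(grp), function(g) {
    others <- setdiff(levels(grp), g)
    rownames(m$counts)[det[, g] >= 1 &
                         rowSums(det[, others, drop = FALSE]) == 0]
  })
  names(sets) <- levels(grp)
  list(exclusive_to = sets,
       detection_rule = "abundance > 0 in >= 1 sample of the group and in 0 samples of every other group")
}

#' Run the full differential-abundance pipeline
#'
#' Orchestrates the complete analysis on a raw abundance set: flag filtering,
#' sample then protein sparsity filtering, TMM normalization, per-protein
#' fitting of the four count models with the nested LRT cascade, Storey
#' q-values over the treatment p-values of all tested (NB-converged)
#' proteins, DAP calling at `q < q_threshold` (strict), and exclusive-protein
#' detection on the same QC-filtered matrix.
#'
#' @param m A raw [abundance_set] (e.g. from [read_protein_groups()] or
#'   [simulate_abundance()]).
#' @param alpha LRT entry level of the model-selection cascade.
#' @param q_threshold q-value threshold for calling a DAP.
#' @param min_sample_frac,min_protein_frac Sparsity-filter thresholds (see
#'   [filter_sparse_samples()], [filter_sparse_proteins()]).
#' @return A list with `results` (per-protein table sorted by q),
#'   `exclusive` (see [exclusive_proteins()]), `matrix` (the QC-filtered,
#'   normalized [abundance_set]) and `report` (stage-by-stage counts).
#' @export
run_dap_pipeline <- function(m, alpha = 0.05, q_threshold = 0.05,
                             min_sample_frac = 0.01, min_protein_frac = 0.10) {
  stopifnot(inherits(m, "abundance_set"))
  qc <- filter_flagged_proteins(m)
  qc <- filter_sparse_samples(qc, min_sample_frac)
  qc <- filter_sparse_proteins(qc, min_protein_frac)
  qc <- tmm_normalize(qc)
  offset <- log(effective_lib_sizes(qc))
  design <- qc$samples

  specs <- lapply(c("NB", "ZINB_basic", "ZINB_TRT", "ZINB_full"), model_spec)
  names(specs) <- vapply(specs, `[[`, "", "name")

  ids <- rownames(qc$counts)
  rows <- vector("list", length(ids))
  excluded <- character(0)
  for (i in seq_along(ids)) {
    y <- qc$counts[i, ]
    cache <- new.env(parent = emptyenv())
    get_fit <- function(nm) {
      if (!is.null(cache[[nm]])) return(cache[[nm]])
      f <- suppressWarnings(fit_model(y, offset, design, specs[[nm]]))
      cache[[nm]] <- f
      f
    }
    sel <- tryCatch(select_cascade(get_fit, alpha = alpha),
                    zinbdap_no_nb_fit = function(e) NULL)
    if (is.null(sel)) {
      excluded <- c(excluded, ids[i])
      next
    }
    entry <- sel$lrt_chain[["NB vs ZINB_basic"]]
    rows[[i]] <- data.frame(
      protein_id = ids[i],
      selected_model = sel$selected_model,
      zi_entry_p = if (is.null(entry)) NA_real_ else entry$p,
      treatment_p = sel$treatment_p,
      ln_fc = sel$ln_fc,
      ci95_low = unname(sel$ci95["lower"]),
      ci95_high = unname(sel$ci95["upper"]),
      se_finite = sel$se_finite,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(results)) stop("no protein could be tested (no NB fit converged)")

  qv <- qvalues(results$treatment_p)
  pi0 <- attr(qv, "pi0")
  results$treatment_q <- as.numeric(qv)
  # a selected model without a finite treatment SE is reported, never a DAP
  results$is_dap <- !is.na(results$treatment_q) &
    results$treatment_q < q_threshold & results$se_finite
  results <- results[order(results$treatment_q, results$treatment_p), ]
  rownames(results) <- NULL

  excl <- exclusive_proteins(qc)
  report <- list(
    input = list(proteins = nrow(m$counts), samples = ncol(m$counts)),
    flag_filter = qc$log$flag_filter,
    sample_filter = qc$log$sample_filter,
    protein_filter = qc$log$protein_filter,
    tmm = qc$log$tmm,
    tested = nrow(results),
    excluded_nonconverged = excluded,
    pi0 = pi0,
    n_dap = sum(results$is_dap),
    exclusive_counts = vapply(excl$exclusive_to, length, integer(1)),
    exclusive_on_same_matrix = TRUE,
    selected_model_counts = table(results$selected_model))
  list(results = results, exclusive = excl, matrix = qc, report = report)
}
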