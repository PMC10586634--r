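#' Construct a protein abundance set
#'
#' Container for a proteins-by-samples label-free abundance matrix together
#' with the sample design, MaxQuant-style per-protein QC flags, library sizes
#' and TMM normalization factors. Zeros are meaningful (protein not detected
#' in that sample). Modelled on the `DGEList` idiom: `$counts` is the matrix,
#' `$samples` carries per-sample metadata including `lib.size` (column sum of
#' the retained matrix) and `norm.factors` (default 1 until
#' [tmm_normalize()] is run).
#'
#' @param counts Numeric matrix, proteins x samples, nonnegative, with unique
#'   rownames (protein IDs).
#' @param samples Design `data.frame` with one row per column of `counts`
#'   (columns `sample_id`, `treatment`, and optionally `gestation_group`,
#'   `fetal_sex`, `initial_bw_kg`). Row order must match the columns.
#' @param flags `data.frame` with logical columns `contaminant`, `reverse`,
#'   `only_by_site`, one row per protein; defaults to all-`FALSE`.
#' @return An object of class `"abundance_set"`.
#' @export
abundance_set <- function(counts, samples, flags = NULL) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    format_error("abundance values must be finite and nonnegative")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("PTN%05d", seq_len(nrow(counts)))
  if (anyDuplicated(rownames(counts)))
    format_error("protein IDs (rownames) must be unique")
  if (!is.data.frame(samples) || nrow(samples) != ncol(counts))
    format_error("`samples` must be a data.frame with one row per sample column")
  if (is.null(samples$sample_id)) samples$sample_id <- colnames(counts)
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample_id
  if (is.null(flags)) {
    flags <- data.frame(contaminant = logical(nrow(counts)),
                        reverse = logical(nrow(counts)),
                        only_by_site = logical(nrow(counts)))
  }
  need <- c("contaminant", "reverse", "only_by_site")
  miss <- setdiff(need, names(flags))
  if (length(miss))
    format_error(paste("missing flag column(s):", paste(miss, collapse = ", ")))
  if (nrow(flags) != nrow(counts))
    format_error("`flags` must have one row per protein")
  rownames(flags) <- rownames(counts)
  samples$lib.size <- colSums(counts)
  if (is.null(samples$norm.factors)) samples$norm.factors <- rep(1, ncol(counts))
  structure(list(counts = counts, samples = samples,
                 flags = flags[need], log = list()),
            class = "abundance_set")
}

#' @export
print.abundance_set <- function(x, ...) {
  cat(sprintf("abundance_set: %d proteins x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$samples$treatment))
    print(table(treatment = x$samples$treatment))
  if (length(x$log)) cat("QC steps applied:", paste(names(x$log), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.abundance_set <- function(x) dim(x$counts)

subset_abundance <- function(m, i = NULL, j = NULL) {
  if (!is.null(i)) {
    m$counts <- m$counts[i, , drop = FALSE]
    m$flags <- m$flags[i, , drop = FALSE]
    if (!is.null(m$truth)) m$truth <- m$truth[i, , drop = FALSE]
  }
  if (!is.null(j)) {
    m$counts <- m$counts[, j, drop = FALSE]
    m$samples <- m$samples[j, , drop = FALSE]
    m$samples$treatment <- droplevels(m$samples$treatment)
  }
  m$samples$lib.size <- colSums(m$counts)
  m
}

#' Effective (normalized) library sizes
#'
#' @param m An [abundance_set].
#' @return `lib.size * norm.factors` per sample.
#' @export
effective_lib_sizes <- function(m) {
  stats::setNames(m$samples$lib.size * m$samples$norm.factors,
                  m$samples$sample_id)
}

#' Remove contaminant, reverse and only-identified-by-site proteins
#'
#' Drops every protein flagged as a potential contaminant, a reverse
#' (decoy) sequence, or identified only by a modification site, and records
#' the per-flag removal counts in the QC log.
#'
#' @param m An [abundance_set] with flag columns.
#' @return The filtered [abundance_set].
#' @export
filter_flagged_proteins <- function(m) {
  stopifnot(inherits(m, "abundance_set"))
  need <- c("contaminant", "reverse", "only_by_site")
  miss <- setdiff(need, names(m$flags))
  if (length(miss))
    format_error(paste("missing flag column(s):", paste(miss, collapse = ", ")))
  drop <- m$flags$contaminant | m$flags$reverse | m$flags$only_by_site
  out <- subset_abundance(m, i = !drop)
  out$log$flag_filter <- list(
    removed = sum(drop),
    contaminant = sum(m$flags$contaminant),
    reverse = sum(m$flags$reverse),
    only_by_site = sum(m$flags$only_by_site),
    retained = sum(!drop))
  out
}

#' Remove samples in which too few proteins were detected
#'
#' A protein counts as detected in a sample when its abundance is strictly
#' positive. Samples whose detected fraction of the current protein panel is
#' below `min_fraction` (default 1%) are removed; this is applied before the
#' protein sparsity filter.
#'
#' @param m An [abundance_set].
#' @param min_fraction Minimum detected fraction to retain a sample.
#' @return The filtered [abundance_set]; removed sample IDs in the QC log.
#' @export
filter_sparse_samples <- function(m, min_fraction = 0.01) {
  stopifnot(inherits(m, "abundance_set"))
  if (nrow(m$counts) == 0) format_error("matrix has no proteins")
  frac <- colSums(m$counts > 0) / nrow(m$counts)
  keep <- frac >= min_fraction
  if (!any(keep)) stop("sample QC removed every sample")
  out <- subset_abundance(m, j = keep)
  out$log$sample_filter <- list(
    removed_ids = m$samples$sample_id[!keep],
    removed = sum(!keep), retained = sum(keep),
    min_fraction = min_fraction)
  out
}

#' Remove proteins detected in too few samples
#'
#' Removes proteins detected (abundance > 0) in fewer than
#' `ceiling(min_fraction * n_samples)` samples. With the default 10% and 22
#' samples this keeps proteins seen in at least 3 samples, i.e. removes those
#' present in 2 or fewer.
#'
#' @param m An [abundance_set], sample QC already applied.
#' @param min_fraction Minimum detected fraction of samples to retain a
#'   protein.
#' @return The filtered [abundance_set].
#' @export
filter_sparse_proteins <- function(m, min_fraction = 0.10) {
  stopifnot(inherits(m, "abundance_set"))
  min_n <- ceiling(min_fraction * ncol(m$counts))
  det <- rowSums(m$counts > 0)
  keep <- det >= min_n
  if (!any(keep)) stop("protein QC removed every protein")
  out <- subset_abundance(m, i = keep)
  out$log$protein_filter <- list(
    removed = sum(!keep), retained = sum(keep),
    min_fraction = min_fraction, min_samples = min_n)
  out
}

#' TMM normalization factors
#'
#' Computes trimmed-mean-of-M-values scaling factors (Robinson & Oshlack):
#' per-protein log2 abundance ratios against a reference sample, computed on
#' library-size-normalized values with zeros excluded pairwise, double-trimmed
#' on M (log-ratio) and A (average log-abundance) and precision-weighted; the
#' factors are rescaled to have geometric mean 1. The reference defaults to
#' the sample whose upper quartile of normalized abundance is closest to the
#' mean upper quartile. Computation is delegated to edgeR's TMM
#' implementation.
#'
#' @param m A QC-filtered [abundance_set] with positive library sizes.
#' @param trim_m Trim proportion on the M values (default 0.30).
#' @param trim_a Trim proportion on the A values (default 0.05).
#' @param reference Optional reference `sample_id`; default picks the
#'   upper-quartile-closest-to-mean sample.
#' @return The [abundance_set] with `samples$norm.factors` filled in; the
#'   normalized library size is `lib.size * norm.factors`
#'   (see [effective_lib_sizes()]).
#' @export
tmm_normalize <- function(m, trim_m = 0.30, trim_a = 0.05, reference = NULL) {
  stopifnot(inherits(m, "abundance_set"))
  counts <- m$counts
  lib <- m$samples$lib.size
  if (any(lib <= 0)) stop("library sizes must be positive; run sample QC first")
  ref_col <- if (is.null(reference)) {
    uq <- apply(sweep(counts, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
    which.min(abs(uq - mean(uq)))
  } else {
    ref_col <- match(reference, m$samples$sample_id)
    if (is.na(ref_col)) stop("unknown reference sample: ", reference)
    ref_col
  }
  co_det <- colSums(counts > 0 & counts[, ref_col] > 0)
  if (any(co_det == 0)) {
    bad <- m$samples$sample_id[which(co_det == 0)[1]]
    stop("sample ", bad, " shares no detected proteins with the reference sample")
  }
  f <- edgeR::calcNormFactors(counts, lib.size = lib, method = "TMM",
                              refColumn = ref_col,
                              logratioTrim = trim_m, sumTrim = trim_a)
  if (any(!is.finite(f)))
    stop("TMM factor not finite for sample ",
         m$samples$sample_id[which(!is.finite(f))[1]])
  m$samples$norm.factors <- as.numeric(f)
  m$log$tmm <- list(reference = m$samples$sample_id[ref_col],
                    trim_m = trim_m, trim_a = trim_a)
  m
}
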