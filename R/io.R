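# Readers and writers for the MaxQuant-style protein-groups dialect and the
# sample design sheet.

#' Read a protein-groups abundance table
#'
#' Accepts the tab-delimited MaxQuant "proteinGroups" dialect: a
#' `"Protein IDs"` column, one abundance column per sample, and the flag
#' columns `"Potential contaminant"`, `"Reverse"` and
#' `"Only identified by site"` coded as `"+"` or empty. An `.xlsx` file
#' (first sheet, header row of sample IDs) is also accepted when the readxl
#' package is available, to accommodate supplementary-dataset-style input.
#'
#' @param file Path to a `.tsv`/`.txt` (tab-delimited) or `.xlsx` file.
#' @param design Sample design `data.frame` (see [read_design()]); its
#'   `sample_id` values select and order the abundance columns.
#' @return An [abundance_set].
#' @export
read_protein_groups <- function(file, design) {
  if (grepl("\\.xlsx$", file, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading .xlsx requires the readxl package")
    tab <- as.data.frame(readxl::read_excel(file, sheet = 1),
                         check.names = FALSE)
  } else {
    tab <- utils::read.delim(file, check.names = FALSE,
                             stringsAsFactors = FALSE)
  }
  if (!"Protein IDs" %in% names(tab))
    format_error("missing column: Protein IDs")
  miss <- setdiff(design$sample_id, names(tab))
  if (length(miss))
    format_error(paste("missing abundance column(s):",
                       paste(miss, collapse = ", ")))
  counts <- as.matrix(tab[, design$sample_id, drop = FALSE])
  storage.mode(counts) <- "double"
  rownames(counts) <- tab[["Protein IDs"]]
  plus <- function(col) {
    if (!col %in% names(tab))
      format_error(paste("missing flag column:", col))
    !is.na(tab[[col]]) & tab[[col]] == "+"
  }
  flags <- data.frame(contaminant = plus("Potential contaminant"),
                      reverse = plus("Reverse"),
                      only_by_site = plus("Only identified by site"))
  abundance_set(counts, design, flags)
}

#' Write an abundance set in the protein-groups dialect
#'
#' @param m An [abundance_set].
#' @param file Output path (tab-delimited text).
#' @export
write_protein_groups <- function(m, file) {
  stopifnot(inherits(m, "abundance_set"))
  mark <- function(x) ifelse(x, "+", "")
  tab <- data.frame(`Protein IDs` = rownames(m$counts),
                    check.names = FALSE, stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(m$counts, check.names = FALSE))
  tab[["Potential contaminant"]] <- mark(m$flags$contaminant)
  tab[["Reverse"]] <- mark(m$flags$reverse)
  tab[["Only identified by site"]] <- mark(m$flags$only_by_site)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a sample design sheet
#'
#' CSV with columns `sample_id`, `treatment` (CON/PRU), and optionally
#' `gestation_group`, `fetal_sex`, `initial_bw_kg`. Factor reference levels
#' are CON, gestation group 1 and the first sex level alphabetically
#' (female first as `"F"`/`"M"`).
#'
#' @param file CSV path.
#' @return A `data.frame` with factor-coded design columns.
#' @export
read_design <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("sample_id", "treatment")
  miss <- setdiff(need, names(d))
  if (length(miss))
    format_error(paste("missing design column(s):", paste(miss, collapse = ", ")))
  d$treatment <- factor(d$treatment, levels = c("CON", "PRU"))
  if (anyNA(d$treatment))
    format_error("treatment must be CON or PRU")
  if (!is.null(d$gestation_group))
    d$gestation_group <- factor(d$gestation_group)
  if (!is.null(d$fetal_sex))
    d$fetal_sex <- factor(d$fetal_sex)
  d
}

#' Write a sample design sheet
#' @param design Design `data.frame`.
#' @param file Output CSV path.
#' @export
write_design <- function(design, file) {
  utils::write.csv(design, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
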