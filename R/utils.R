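# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that simulation helpers do
#' not perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Seed for the per-protein random stream
#'
#' Each protein gets its own stream derived from the base seed and the protein
#' index, so that adding proteins never perturbs earlier ones. Kept within the
#' 32-bit integer range.
#' @noRd
protein_seed <- function(seed, p) {
  (as.numeric(seed) * 1009 + p) %% 2147483647
}

config_error <- function(field, msg) {
  stop(structure(
    class = c("zinbdap_config_error", "error", "condition"),
    list(message = sprintf("invalid `%s`: %s", field, msg), call = sys.call(-1))
  ))
}

format_error <- function(msg) {
  stop(structure(
    class = c("zinbdap_format_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
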