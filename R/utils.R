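# Internal helpers shared across modules.

#' Experimental conditions
#'
#' The three growth-temperature conditions, in fixed order: `LOW` (22 degC
#' cold stress), `OPT` (35 degC optimal growth) and `HIGH` (40 degC heat
#' stress).
#'
#' @return Character vector `c("LOW", "OPT", "HIGH")`.
#' @export
conditions <- function() c("LOW", "OPT", "HIGH")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_ <- function(...) stop(..., call. = FALSE)

# Deterministic sub-seed derivation: one user-facing seed governs all
# sub-generators. Stage k gets seed (seed * 7919 + k) mod (2^31 - 1),
# kept inside 32-bit integer range.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 250000 * 7919 + k) %% 2147483647L)
}

# sorted-by-name convenience used for deterministic outputs
sort_df <- function(df, cols) {
  df[do.call(order, df[cols]), , drop = FALSE]
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "", ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
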