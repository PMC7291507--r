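#' Analysis thresholds
#'
#' Bundles the cut-offs used throughout the pipeline. Defaults are the
#' standard choices for this kind of temperature-stress proteome analysis:
#' intensities below 3x the noise estimate are discarded, differential
#' expression requires p <= 0.05 and a fold-change of at least 1.5 (both
#' inclusive), and reciprocal-best-hit orthology requires an e-value
#' strictly below 1e-10.
#'
#' @param noise_multiplier Signal threshold in noise units; an intensity is
#'   kept only when `intensity >= noise_multiplier * noise` (strictly lower
#'   values are removed). Default 3.
#' @param p_cutoff Significance cut-off for differential tests, inclusive.
#'   Default 0.05.
#' @param fc_cutoff Fold-change cut-off on the linear scale, inclusive;
#'   must be >= 1. Default 1.5.
#' @param rbh_evalue Strict upper bound on the e-value of both directions
#'   of a reciprocal best hit. Default 1e-10.
#' @param adjust_p Apply Benjamini-Hochberg adjustment to differential-test
#'   p-values before calling. Default `FALSE` (raw p-values, the headline
#'   path).
#'
#' @return An object of class `"bilevel_thresholds"`.
#' @examples
#' thresholds()
#' thresholds(fc_cutoff = 2)
#' @export
thresholds <- function(noise_multiplier = 3, p_cutoff = 0.05,
                       fc_cutoff = 1.5, rbh_evalue = 1e-10,
                       adjust_p = FALSE) {
  for (v in c(noise_multiplier = noise_multiplier, p_cutoff = p_cutoff,
              fc_cutoff = fc_cutoff, rbh_evalue = rbh_evalue)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop_("all thresholds must be single, strictly positive numbers")
  }
  if (fc_cutoff < 1) stop_("'fc_cutoff' must be >= 1 (linear fold units)")
  structure(list(noise_multiplier = noise_multiplier, p_cutoff = p_cutoff,
                 fc_cutoff = fc_cutoff, rbh_evalue = rbh_evalue,
                 adjust_p = isTRUE(adjust_p)),
            class = "bilevel_thresholds")
}

#' @export
print.bilevel_thresholds <- function(x, ...) {
  cat("Pipeline thresholds\n")
  cat(sprintf("  signal:       intensity >= %g x noise\n", x$noise_multiplier))
  cat(sprintf("  significance: p <= %g%s\n", x$p_cutoff,
              if (x$adjust_p) " (BH-adjusted)" else ""))
  cat(sprintf("  fold change:  >= %g (or <= 1/%g)\n", x$fc_cutoff, x$fc_cutoff))
  cat(sprintf("  RBH e-value:  < %g\n", x$rbh_evalue))
  invisible(x)
}
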