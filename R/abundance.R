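#' Protein abundance matrix
#'
#' Container for label-free MS protein intensities across the three
#' temperature conditions with per-measurement noise estimates. Rows are
#' proteins (unique accessions), columns are (condition, replicate)
#' measurements. Missing intensities are `NA`.
#'
#' @param intensity Numeric matrix, proteins x measurements; row names are
#'   accessions; values are non-negative MS intensities (arbitrary units)
#'   or `NA`.
#' @param noise Numeric matrix of the same dimension (per-measurement
#'   noise), or a numeric vector of length `ncol(intensity)` (one noise
#'   estimate per (condition, replicate) channel, recycled down columns).
#' @param condition Character vector, one of [conditions()] per column.
#' @param replicate Integer vector of replicate indices per column.
#'
#' @return An object of class `"abundance_matrix"`: a list with elements
#'   `intensity`, `noise`, `condition`, `replicate`.
#' @seealso [read_abundance()], [apply_signal_threshold()],
#'   [test_differential()]
#' @export
abundance_matrix <- function(intensity, noise, condition, replicate) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop_("'intensity' must be a numeric matrix")
  if (is.null(rownames(intensity)))
    stop_("'intensity' must have accession row names")
  if (anyDuplicated(rownames(intensity)))
    stop_("accessions (row names) must be unique")
  if (any(intensity < 0, na.rm = TRUE))
    stop_("intensities must be non-negative")
  if (length(condition) != ncol(intensity))
    stop_("'condition' must have one entry per column")
  if (!all(condition %in% conditions()))
    stop_("'condition' entries must be among: ",
          paste(conditions(), collapse = ", "))
  if (length(replicate) != ncol(intensity))
    stop_("'replicate' must have one entry per column")
  if (!all(table(factor(condition, conditions())) >= 1L))
    stop_("every condition needs at least one replicate column")
  if (is.vector(noise))
    noise <- matrix(rep(noise, each = nrow(intensity)),
                    nrow = nrow(intensity), dimnames = dimnames(intensity))
  if (!identical(dim(noise), dim(intensity)))
    stop_("'noise' must match the dimensions of 'intensity'")
  if (any(noise < 0, na.rm = TRUE)) stop_("noise estimates must be non-negative")
  colnames(intensity) <- colnames(noise) <-
    paste0(condition, ".", as.integer(replicate))
  structure(list(intensity = intensity, noise = noise,
                 condition = as.character(condition),
                 replicate = as.integer(replicate)),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("Abundance matrix: %d proteins x %d measurements\n",
              nrow(x$intensity), ncol(x$intensity)))
  tab <- table(factor(x$condition, conditions()))
  cat("  replicates: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  missing values: %d\n", sum(is.na(x$intensity))))
  flog <- attr(x, "filter_log")
  if (!is.null(flog))
    cat(sprintf("  signal-filtered: %d values removed (< %g x noise)\n",
                flog$n_removed, flog$noise_multiplier))
  invisible(x)
}

#' Read a long-format abundance TSV
#'
#' Expects columns `accession`, `condition` (LOW|OPT|HIGH), `replicate`
#' (integer), `intensity` and `noise`; missing intensities are empty
#' fields.
#'
#' @param path Path to a tab-separated file (UTF-8, header required).
#' @return An [abundance_matrix()].
#' @export
read_abundance <- function(path) {
  df <- read_tsv(path)
  need <- c("accession", "condition", "replicate", "intensity", "noise")
  if (!all(need %in% names(df)))
    stop_("abundance TSV needs columns: ", paste(need, collapse = ", "))
  df$intensity <- suppressWarnings(as.numeric(df$intensity))
  df$noise <- suppressWarnings(as.numeric(df$noise))
  acc <- sort(unique(df$accession))
  chan <- unique(df[c("condition", "replicate")])
  chan <- chan[order(match(chan$condition, conditions()), chan$replicate), ]
  key <- paste0(chan$condition, ".", chan$replicate)
  int <- noi <- matrix(NA_real_, length(acc), nrow(chan),
                       dimnames = list(acc, key))
  idx <- cbind(match(df$accession, acc),
               match(paste0(df$condition, ".", df$replicate), key))
  int[idx] <- df$intensity
  noi[idx] <- df$noise
  abundance_matrix(int, noi, chan$condition, chan$replicate)
}

#' Write an abundance matrix as a long-format TSV
#'
#' @param x An [abundance_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(x, path) {
  long <- data.frame(
    accession = rep(rownames(x$intensity), times = ncol(x$intensity)),
    condition = rep(x$condition, each = nrow(x$intensity)),
    replicate = rep(x$replicate, each = nrow(x$intensity)),
    intensity = as.vector(x$intensity),
    noise = as.vector(x$noise))
  long$intensity[is.na(long$intensity)] <- ""
  write_tsv(long, path)
}

#' Remove intensities below the signal threshold
#'
#' Sets to missing every intensity strictly lower than
#' `noise_multiplier x noise` (equality is kept); all other values are
#' unchanged. The operation is idempotent. The number of removed values is
#' recorded in the `"filter_log"` attribute of the result.
#'
#' @param x An [abundance_matrix()].
#' @param thr A [thresholds()] object.
#' @return The filtered `abundance_matrix`, with attribute `"filter_log"`
#'   (a list with `n_removed` and `noise_multiplier`).
#' @examples
#' m <- abundance_matrix(
#'   matrix(c(299, 300, 1000, 900, 500, 450), 1,
#'          dimnames = list("P1", NULL)),
#'   noise = rep(100, 6),
#'   condition = rep(c("LOW", "OPT", "HIGH"), each = 2),
#'   replicate = rep(1:2, 3))
#' filtered <- apply_signal_threshold(m, thresholds())
#' attr(filtered, "filter_log")$n_removed  # 1: the 299 (299 < 3 * 100)
#' @export
apply_signal_threshold <- function(x, thr = thresholds()) {
  stopifnot(inherits(x, "abundance_matrix"))
  present <- !is.na(x$intensity)
  no_noise <- present & is.na(x$noise)
  if (any(no_noise)) {
    bad <- which(no_noise, arr.ind = TRUE)[1L, ]
    stop_(sprintf("missing noise estimate for measurement %s / %s",
                  rownames(x$intensity)[bad[1L]],
                  colnames(x$intensity)[bad[2L]]))
  }
  drop <- present & (x$intensity < thr$noise_multiplier * x$noise)
  x$intensity[drop] <- NA_real_
  attr(x, "filter_log") <- list(n_removed = sum(drop),
                                noise_multiplier = thr$noise_multiplier)
  x
}

# columns of an abundance matrix belonging to one condition
cond_cols <- function(x, condition) which(x$condition == condition)

#' Per-condition detection presence
#'
#' A protein counts as identified under a condition when at least one
#' replicate intensity is present (after signal filtering).
#'
#' @param x An [abundance_matrix()].
#' @return Data frame with columns `accession`, `LOW`, `OPT`, `HIGH`
#'   (logical).
#' @export
presence_by_condition <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  out <- data.frame(accession = rownames(x$intensity),
                    stringsAsFactors = FALSE)
  for (cc in conditions())
    out[[cc]] <- rowSums(!is.na(x$intensity[, cond_cols(x, cc), drop = FALSE])) > 0
  out
}

# two-sided pooled-variance (Student) t-test on log2 intensities;
# returns NA p when either group has < 2 values
pooled_t_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) return(NA_real_)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) return(if (mean(a) == mean(b)) 1 else 0)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * stats::pt(-abs(tstat), df = na + nb - 2)
}

#' Differential-expression test between a stress condition and the optimum
#'
#' For every protein the fold-change is the ratio of linear-scale mean
#' intensities, stress over optimal, and the p-value comes from a
#' two-sided pooled-variance (Student) t-test on the log2 intensities.
#' Calls use inclusive thresholds: `UP` when `fold_change >= fc_cutoff`
#' and `p <= p_cutoff`; `DOWN` when `fold_change <= 1/fc_cutoff` and
#' `p <= p_cutoff`; otherwise `NOT_SIGNIFICANT`. Proteins with fewer than
#' two present replicates in either condition (or a non-positive optimal
#' mean) are `UNTESTABLE`.
#'
#' @param x A signal-filtered [abundance_matrix()].
#' @param stress `"LOW"` or `"HIGH"`.
#' @param thr A [thresholds()] object. With `adjust_p = TRUE`,
#'   Benjamini-Hochberg adjusted p-values are used for the calls (and
#'   reported).
#' @return Data frame of class `"expression_results"` with columns
#'   `accession`, `contrast`, `fold_change`, `log2_fc`, `p_value`, `call`,
#'   `reason`.
#' @export
test_differential <- function(x, stress = c("LOW", "HIGH"),
                              thr = thresholds()) {
  stopifnot(inherits(x, "abundance_matrix"))
  stress <- match.arg(stress)
  s_cols <- cond_cols(x, stress)
  o_cols <- cond_cols(x, "OPT")
  acc <- rownames(x$intensity)
  n <- length(acc)
  fc <- l2 <- p <- rep(NA_real_, n)
  call <- rep("UNTESTABLE", n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    sv <- x$intensity[i, s_cols]; sv <- sv[!is.na(sv) & sv > 0]
    ov <- x$intensity[i, o_cols]; ov <- ov[!is.na(ov) & ov > 0]
    if (length(sv) < 2L || length(ov) < 2L) {
      reason[i] <- "fewer than 2 present replicates in a condition"
      next
    }
    om <- mean(ov)
    if (om <= 0) { reason[i] <- "non-positive optimal mean"; next }
    fc[i] <- mean(sv) / om
    l2[i] <- log2(fc[i])
    p[i] <- pooled_t_p(log2(sv), log2(ov))
    call[i] <- "NOT_SIGNIFICANT"
  }
  if (thr$adjust_p) p <- stats::p.adjust(p, method = "BH")
  testable <- call != "UNTESTABLE"
  up <- testable & fc >= thr$fc_cutoff & p <= thr$p_cutoff
  dn <- testable & fc <= 1 / thr$fc_cutoff & p <= thr$p_cutoff
  call[which(up)] <- "UP"
  call[which(dn)] <- "DOWN"
  out <- data.frame(accession = acc,
                    contrast = paste0(stress, "_vs_OPT"),
                    fold_change = fc, log2_fc = l2, p_value = p,
                    call = call, reason = reason,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("expression_results", "data.frame")
  out
}

#' @export
print.expression_results <- function(x, ...) {
  cat(sprintf("Differential expression, %s: %d proteins\n",
              x$contrast[1] %||% "?", nrow(x)))
  print(table(factor(x$call, c("UP", "DOWN", "NOT_SIGNIFICANT", "UNTESTABLE"))))
  invisible(x)
}

#' Write differential-expression results as TSV
#'
#' @param res An `"expression_results"` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_expression_results <- function(res, path) {
  write_tsv(res[c("accession", "contrast", "fold_change", "log2_fc",
                  "p_value", "call")], path)
}

#' One-group t-test against zero
#'
#' Single-condition significance of detection: a one-sample, two-sided
#' t-test of the log2 intensities against zero, per protein. Reported as a
#' statistic only; headline calls derive from the pairwise stress-vs-OPT
#' contrasts.
#'
#' @param x An [abundance_matrix()].
#' @param condition One of [conditions()].
#' @return Data frame with `accession`, `n`, `t`, `p_value`.
#' @export
t_test_against_zero <- function(x, condition) {
  stopifnot(inherits(x, "abundance_matrix"), condition %in% conditions())
  cols <- cond_cols(x, condition)
  res <- t(apply(x$intensity[, cols, drop = FALSE], 1L, function(v) {
    v <- v[!is.na(v) & v > 0]
    if (length(v) < 2L) return(c(length(v), NA_real_, NA_real_))
    ht <- stats::t.test(log2(v), mu = 0)
    c(length(v), unname(ht$statistic), ht$p.value)
  }))
  data.frame(accession = rownames(x$intensity), n = as.integer(res[, 1]),
             t = res[, 2], p_value = res[, 3], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' One-way ANOVA across the three conditions
#'
#' Reported statistic only: an F-test of log2 intensity against condition
#' for each protein with at least two present replicates in each of at
#' least two conditions.
#'
#' @param x An [abundance_matrix()].
#' @return Data frame with `accession`, `f_statistic`, `p_value`.
#' @export
anova_across_conditions <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  acc <- rownames(x$intensity)
  out <- data.frame(accession = acc, f_statistic = NA_real_,
                    p_value = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(acc)) {
    keep <- !is.na(x$intensity[i, ]) & x$intensity[i, ] > 0
    if (sum(keep) < 4L) next
    g <- factor(x$condition[keep], conditions())
    if (sum(table(g) >= 2L) < 2L) next
    fit <- stats::aov(log2(x$intensity[i, keep]) ~ droplevels(g))
    s <- summary(fit)[[1L]]
    out$f_statistic[i] <- s[["F value"]][1L]
    out$p_value[i] <- s[["Pr(>F)"]][1L]
  }
  out
}

#' Classify cross-condition regulation
#'
#' Deterministic mapping of the pair of calls (cold contrast, heat
#' contrast) onto nine regulation classes: `UP_UP`, `DOWN_DOWN`,
#' `UP22_DOWN40`, `DOWN22_UP40`, `LOW_ONLY_UP`, `LOW_ONLY_DOWN`,
#' `HIGH_ONLY_UP`, `HIGH_ONLY_DOWN` and `NONE`.
#'
#' @param low_call,high_call Calls from [test_differential()] for the LOW
#'   and HIGH contrasts (`UP`, `DOWN`, `NOT_SIGNIFICANT`, `UNTESTABLE`).
#'   Vectorised.
#' @return Character vector of regulation classes.
#' @examples
#' classify_regulation("UP", "DOWN")            # "UP22_DOWN40"
#' classify_regulation("UP", "NOT_SIGNIFICANT") # "LOW_ONLY_UP"
#' @export
classify_regulation <- function(low_call, high_call) {
  calls <- c("UP", "DOWN", "NOT_SIGNIFICANT", "UNTESTABLE")
  if (!all(low_call %in% calls) || !all(high_call %in% calls))
    stop_("calls must be among: ", paste(calls, collapse = ", "))
  lo <- ifelse(low_call %in% c("UP", "DOWN"), low_call, "NONE")
  hi <- ifelse(high_call %in% c("UP", "DOWN"), high_call, "NONE")
  key <- paste(lo, hi, sep = "|")
  map <- c("UP|UP" = "UP_UP", "DOWN|DOWN" = "DOWN_DOWN",
           "UP|DOWN" = "UP22_DOWN40", "DOWN|UP" = "DOWN22_UP40",
           "UP|NONE" = "LOW_ONLY_UP", "DOWN|NONE" = "LOW_ONLY_DOWN",
           "NONE|UP" = "HIGH_ONLY_UP", "NONE|DOWN" = "HIGH_ONLY_DOWN",
           "NONE|NONE" = "NONE")
  unname(map[key])
}

#' Regulation classes for a pair of contrast result tables
#'
#' @param low_results,high_results `"expression_results"` for the LOW and
#'   HIGH contrasts; must cover the same accessions.
#' @return Data frame with `accession` and `class`.
#' @export
classify_regulation_table <- function(low_results, high_results) {
  lo <- low_results[order(low_results$accession), ]
  hi <- high_results[order(high_results$accession), ]
  if (!identical(lo$accession, hi$accession))
    stop_("accession sets of the two contrasts differ")
  data.frame(accession = lo$accession,
             class = classify_regulation(lo$call, hi$call),
             stringsAsFactors = FALSE)
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative average-linkage clustering (Euclidean distance) of the
#' per-condition mean log2 intensity profiles, the standard companion of
#' an expression heatmap. Proteins with an all-missing condition are
#' excluded with a warning.
#'
#' @param x An [abundance_matrix()].
#' @return An object of class `"hclust"` with accession labels, plus
#'   attribute `"profiles"` (the matrix clustered).
#' @seealso [write_dendrogram_newick()]
#' @export
cluster_expression_profiles <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  prof <- sapply(conditions(), function(cc) {
    m <- x$intensity[, cond_cols(x, cc), drop = FALSE]
    lm <- log2(ifelse(!is.na(m) & m > 0, m, NA))
    rowMeans(lm, na.rm = TRUE)
  })
  if (is.null(dim(prof))) prof <- matrix(prof, nrow = 1,
                                         dimnames = list(rownames(x$intensity),
                                                         conditions()))
  complete <- stats::complete.cases(prof) & apply(is.finite(prof), 1L, all)
  if (any(!complete))
    warning(sum(!complete), " protein(s) with an incomplete profile excluded",
            call. = FALSE)
  prof <- prof[complete, , drop = FALSE]
  if (nrow(prof) < 2L)
    stop_("need at least 2 proteins with complete condition means")
  hc <- stats::hclust(stats::dist(prof, method = "euclidean"),
                      method = "average")
  attr(hc, "profiles") <- prof
  hc
}

#' Write a dendrogram in Newick format
#'
#' Branch lengths encode the merge heights of the clustering.
#'
#' @param hc An `"hclust"` object (e.g. from
#'   [cluster_expression_profiles()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
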