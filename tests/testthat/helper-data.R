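# Small in-code fixtures.

`%||%` <- function(a, b) if (is.null(a)) b else a

# abundance matrix from per-condition log2 means; 3 replicates each
make_abundance <- function(log2_means, sd = 0, noise = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  acc <- rownames(log2_means)
  nrep <- 3L
  condition <- rep(conditions(), each = nrep)
  replicate <- rep(seq_len(nrep), 3L)
  m <- matrix(NA_real_, nrow(log2_means), length(condition),
              dimnames = list(acc, NULL))
  for (ci in seq_along(conditions())) {
    cols <- which(condition == conditions()[ci])
    m[, cols] <- 2^(log2_means[, ci] +
                      matrix(rnorm(length(acc) * nrep, 0, sd),
                             ncol = nrep))
  }
  abundance_matrix(m, rep(noise, length(condition)), condition, replicate)
}

# a minimal phosphopeptide table row
pep_row <- function(accession, peptide, labels, low = 1, opt = 0, high = 0,
                    prec = 10, prod = 30, mc = 0) {
  data.frame(accession = accession, peptide = peptide, site_labels = labels,
             cond_low = low, cond_opt = opt, cond_high = high,
             precursor_ppm = prec, product_ppm = prod,
             missed_cleavages = mc, stringsAsFactors = FALSE)
}

# expression result row for direct bilevel tests
expr_row <- function(accession, contrast, fc, p,
                     thr = thresholds()) {
  call <- if (is.na(fc) || is.na(p)) "UNTESTABLE"
          else if (fc >= thr$fc_cutoff && p <= thr$p_cutoff) "UP"
          else if (fc <= 1 / thr$fc_cutoff && p <= thr$p_cutoff) "DOWN"
          else "NOT_SIGNIFICANT"
  structure(data.frame(accession = accession, contrast = contrast,
                       fold_change = fc, log2_fc = log2(fc),
                       p_value = p, call = call, reason = NA_character_,
                       stringsAsFactors = FALSE),
            class = c("expression_results", "data.frame"))
}
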