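# Signal filtering, differential testing, regulation classes, clustering.

test_that("signal threshold removes strictly sub-threshold values only", {
  m <- matrix(c(299, 300, 301, 1000, 900, 800, 500, 450, 400), 1,
              dimnames = list("P1", NULL))
  ab <- abundance_matrix(m, rep(100, 9), rep(conditions(), each = 3),
                         rep(1:3, 3))
  f <- apply_signal_threshold(ab, thresholds())
  expect_true(is.na(f$intensity[1, 1]))       # 299 < 300 removed
  expect_equal(f$intensity[1, 2], 300)        # equality kept
  expect_equal(attr(f, "filter_log")$n_removed, 1L)
})

test_that("signal threshold count matches a planted sub-threshold set", {
  set.seed(401)
  n <- 40L  # proteins; 40 of the 400 lowest values planted below 3x noise
  vals <- matrix(runif(400, 1e4, 1e5), n, 10,
                 dimnames = list(sprintf("P%02d", 1:n), NULL))
  low_cells <- sample(length(vals), 40L)
  vals[low_cells] <- runif(40L, 0, 299.99)
  ab <- abundance_matrix(vals[, 1:9], rep(100, 9),
                         rep(conditions(), each = 3), rep(1:3, 3))
  planted <- sum(vals[, 1:9] < 300)
  f <- apply_signal_threshold(ab)
  expect_equal(attr(f, "filter_log")$n_removed, planted)
  # idempotence
  f2 <- apply_signal_threshold(f)
  expect_identical(f2$intensity, f$intensity)
  expect_equal(attr(f2, "filter_log")$n_removed, 0L)
})

test_that("a missing noise estimate is reported with the measurement", {
  m <- matrix(c(500, 600, 700, 800, 900, 950), 1,
              dimnames = list("P9", NULL))
  noise <- matrix(c(100, NA, 100, 100, 100, 100), 1)
  ab <- abundance_matrix(m, noise, rep(conditions(), each = 2), rep(1:2, 3))
  expect_error(apply_signal_threshold(ab), "P9")
})

test_that("identical replicate vectors give fold change 1, not significant", {
  lm <- matrix(c(12, 12, 12), 1, dimnames = list("A", NULL))
  ab <- make_abundance(lm)
  res <- test_differential(ab, "LOW")
  expect_equal(res$fold_change, 1)
  expect_equal(res$call, "NOT_SIGNIFICANT")
  expect_equal(res$p_value, 1)
})

test_that("t statistic and p reproduce the closed-form pooled-t oracle", {
  # log2 intensities {10,12,11} under stress vs {20,22,21} at the optimum
  m <- matrix(NA_real_, 1, 9, dimnames = list("A", NULL))
  m[1, 1:3] <- 2^c(10, 12, 11)   # LOW
  m[1, 4:6] <- 2^c(20, 22, 21)   # OPT
  m[1, 7:9] <- 2^c(20, 22, 21)   # HIGH (unused)
  ab <- abundance_matrix(m, rep(1, 9), rep(conditions(), each = 3),
                         rep(1:3, 3))
  res <- test_differential(ab, "LOW")
  expect_equal(res$fold_change, 2^-10)  # same replicate pattern, scaled
  orc <- t_oracle(c(10, 12, 11), c(20, 22, 21))
  expect_equal(res$p_value, orc$p, tolerance = 1e-12)
  expect_equal(res$call, "DOWN")
})

test_that("fold-change threshold is inclusive at exactly 1.5", {
  m <- matrix(NA_real_, 1, 9, dimnames = list("A", NULL))
  m[1, 4:6] <- c(1000, 1024, 992)            # OPT, tight replicates
  m[1, 1:3] <- 1.5 * c(1000, 1024, 992)      # LOW = exactly 1.5x
  m[1, 7:9] <- c(1000, 1024, 992)
  ab <- abundance_matrix(m, rep(1, 9), rep(conditions(), each = 3),
                         rep(1:3, 3))
  res <- test_differential(ab, "LOW")
  expect_equal(res$fold_change, 1.5)
  expect_true(res$p_value <= 0.05)
  expect_equal(res$call, "UP")
  # and the reciprocal boundary for DOWN
  m2 <- m
  m2[1, 1:3] <- c(1000, 1024, 992) / 1.5
  ab2 <- abundance_matrix(m2, rep(1, 9), rep(conditions(), each = 3),
                          rep(1:3, 3))
  expect_equal(test_differential(ab2, "LOW")$call, "DOWN")
})

test_that("calls agree with an oracle applying the inclusive rules", {
  set.seed(77)
  n <- 60L
  lm <- matrix(17, n, 3, dimnames = list(sprintf("P%02d", 1:n), NULL))
  lm[, 1] <- 17 + sample(c(-1, 0, 1), n, TRUE) * runif(n, 0, 1.2)
  ab <- make_abundance(lm, sd = 0.25, seed = 78)
  res <- test_differential(ab, "LOW", thresholds())
  for (i in seq_len(n)) {
    sv <- log2(ab$intensity[i, 1:3]); ov <- log2(ab$intensity[i, 4:6])
    orc <- t_oracle(sv, ov)
    fc <- mean(2^sv) / mean(2^ov)
    want <- if (fc >= 1.5 && orc$p <= 0.05) "UP"
            else if (fc <= 1 / 1.5 && orc$p <= 0.05) "DOWN"
            else "NOT_SIGNIFICANT"
    expect_equal(res$call[i], want)
    expect_equal(res$p_value[i], orc$p, tolerance = 1e-12)
  }
})

test_that("proteins with under two present replicates are untestable", {
  m <- matrix(c(NA, NA, 500, 600, 700, 800, 900, 950, 970), 1,
              dimnames = list("A", NULL))
  ab <- abundance_matrix(m, rep(1, 9), rep(conditions(), each = 3),
                         rep(1:3, 3))
  res <- test_differential(ab, "LOW")
  expect_equal(res$call, "UNTESTABLE")
  expect_match(res$reason, "replicates")
})

test_that("swapping the contrast inverts the fold change exactly", {
  set.seed(5150)
  lm <- matrix(runif(30, 14, 19), 10, 3,
               dimnames = list(sprintf("P%02d", 1:10), NULL))
  ab <- make_abundance(lm, sd = 0.2, seed = 5151)
  fwd <- test_differential(ab, "LOW")
  # swap LOW and OPT column labels to compute the reversed contrast
  swapped <- ab
  swapped$condition <- c("OPT", "OPT", "OPT", "LOW", "LOW", "LOW",
                         "HIGH", "HIGH", "HIGH")
  rev <- test_differential(swapped, "LOW")
  expect_equal(fwd$fold_change * rev$fold_change, rep(1, 10),
               tolerance = 1e-12)
})

test_that("regulation classification matches hand enumeration on the call grid", {
  calls <- c("UP", "DOWN", "NOT_SIGNIFICANT", "UNTESTABLE")
  # independent oracle: spelled-out decision table
  oracle <- function(lo, hi) {
    lo_reg <- lo %in% c("UP", "DOWN"); hi_reg <- hi %in% c("UP", "DOWN")
    if (lo_reg && hi_reg) {
      if (lo == "UP" && hi == "UP") return("UP_UP")
      if (lo == "DOWN" && hi == "DOWN") return("DOWN_DOWN")
      if (lo == "UP") return("UP22_DOWN40")
      return("DOWN22_UP40")
    }
    if (lo_reg) return(paste0("LOW_ONLY_", lo))
    if (hi_reg) return(paste0("HIGH_ONLY_", hi))
    "NONE"
  }
  for (lo in calls) for (hi in calls)
    expect_equal(classify_regulation(lo, hi), oracle(lo, hi),
                 info = paste(lo, hi))
  expect_error(classify_regulation("SIDEWAYS", "UP"), "calls must be")
})

test_that("classification table rejects mismatched accession sets", {
  a <- expr_row("P1", "LOW_vs_OPT", 2, 0.01)
  b <- expr_row("P2", "HIGH_vs_OPT", 2, 0.01)
  expect_error(classify_regulation_table(a, b), "differ")
})

test_that("profile clustering merges identical profiles first, at height zero", {
  lm <- rbind(A = c(12, 14, 13), B = c(12, 14, 13), C = c(18, 10, 15))
  hc <- cluster_expression_profiles(make_abundance(lm))
  expect_equal(hc$height[1], 0)
  first <- hc$labels[-hc$merge[1, ]]
  expect_setequal(first, c("A", "B"))
})

test_that("average-linkage clustering equals the naive O(n^3) oracle", {
  set.seed(303)
  lm <- matrix(rnorm(15, 15, 2), 5, 3,
               dimnames = list(paste0("P", 1:5), NULL))
  ab <- make_abundance(lm)
  hc <- cluster_expression_profiles(ab)
  prof <- attr(hc, "profiles")
  want <- avg_linkage_cophenetic_oracle(prof)
  got <- as.matrix(stats::cophenetic(hc))[rownames(want), colnames(want)]
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("all-missing profiles are excluded with a warning", {
  lm <- rbind(A = c(12, 14, 13), B = c(13, 12, 14), C = c(15, 11, 12))
  ab <- make_abundance(lm)
  ab$intensity["C", 1:3] <- NA  # no LOW values -> incomplete profile
  expect_warning(hc <- cluster_expression_profiles(ab), "excluded")
  expect_setequal(hc$labels, c("A", "B"))
})

test_that("newick export writes one tree with all labels", {
  lm <- matrix(rnorm(12, 15, 2), 4, 3,
               dimnames = list(paste0("P", 1:4), NULL))
  hc <- cluster_expression_profiles(make_abundance(lm))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(hc, path)
  tr <- ape::read.tree(path)
  expect_setequal(tr$tip.label, paste0("P", 1:4))
})

test_that("single-condition t against zero and ANOVA run as reported statistics", {
  set.seed(99)
  lm <- matrix(runif(9, 14, 18), 3, 3,
               dimnames = list(paste0("P", 1:3), NULL))
  ab <- make_abundance(lm, sd = 0.1, seed = 100)
  tz <- t_test_against_zero(ab, "OPT")
  expect_equal(nrow(tz), 3L)
  expect_true(all(tz$p_value < 0.05))  # log2 intensities far from zero
  av <- anova_across_conditions(ab)
  fit <- stats::aov(log2(ab$intensity[1, ]) ~ factor(ab$condition))
  expect_equal(av$p_value[1], summary(fit)[[1]][["Pr(>F)"]][1],
               tolerance = 1e-10)
})
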