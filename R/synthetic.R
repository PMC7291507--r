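# Synthetic benchmark data with planted ground truth: three-condition
# replicate abundances, condition-dependent phosphopeptide detections,
# orthologous proteome pairs with controlled divergence, and a bait->prey
# template network.

# Robinson-style amino-acid background frequencies used for random
# sequences, so alignment score nulls behave like real proteins.
aa_background <- c(
  A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019, Q = 0.043,
  E = 0.063, G = 0.074, H = 0.022, I = 0.051, L = 0.091, K = 0.057,
  M = 0.022, F = 0.039, P = 0.052, S = 0.071, T = 0.058, W = 0.013,
  Y = 0.032, V = 0.065)

#' Simulation configuration
#'
#' Defines the synthetic study: three temperature conditions with three
#' biological replicates, log-normal intensity noise, planted fold-changes
#' at or above the 1.5-fold reporting cut-off, condition-dependent
#' phosphosite detections, a template proteome with a controlled-divergence
#' orthologous query proteome, and a bait->prey template network.
#'
#' @param seed Integer seed; one seed governs all sub-generators through a
#'   fixed splitting scheme.
#' @param n_proteins Query-species proteins with abundance data (default
#'   200).
#' @param n_template_proteins Template-species proteome size (default 80).
#' @param ortholog_fraction Fraction of template proteins with a planted
#'   1:1 query ortholog (default 0.8).
#' @param divergence Per-site substitution probability applied to planted
#'   orthologs (default 0.05).
#' @param de_fraction Fraction of proteins planted as differentially
#'   expressed, per contrast (default 0.1).
#' @param log2_fc_range Range (min, max) of planted |log2 fold-change|;
#'   the minimum defaults to `log2(1.5)` so every planted positive sits at
#'   or above the reporting cut-off (default `c(log2(1.5), 2)`).
#' @param replicate_sd Replicate standard deviation in log2 units
#'   (default 0.2, the typical label-free MS replicate spread).
#' @param n_replicates Biological replicates per condition (default 3).
#' @param noise_floor Per-measurement noise estimate in intensity units
#'   (default 100).
#' @param low_signal_fraction Fraction of measurements planted below the
#'   3x-noise signal threshold (default 0.02).
#' @param phospho_fraction Fraction of query proteins carrying planted
#'   phosphosites (default 0.2).
#' @param sites_per_protein Integer range of planted sites per
#'   phosphoprotein (default `c(1, 3)`).
#' @param detection_prob Per-condition detection probability of each
#'   phosphopeptide (default 0.8 for each of LOW/OPT/HIGH).
#' @param n_template_edges Bait->prey edges in the template network
#'   (default 60).
#' @param protein_length Range of protein lengths (default `c(80, 160)`).
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_proteins = 200L,
                       n_template_proteins = 80L, ortholog_fraction = 0.8,
                       divergence = 0.05, de_fraction = 0.1,
                       log2_fc_range = c(log2(1.5), 2),
                       replicate_sd = 0.2, n_replicates = 3L,
                       noise_floor = 100, low_signal_fraction = 0.02,
                       phospho_fraction = 0.2, sites_per_protein = c(1L, 3L),
                       detection_prob = c(LOW = 0.8, OPT = 0.8, HIGH = 0.8),
                       n_template_edges = 60L,
                       protein_length = c(80L, 160L)) {
  cfg <- list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
              n_template_proteins = as.integer(n_template_proteins),
              ortholog_fraction = ortholog_fraction, divergence = divergence,
              de_fraction = de_fraction, log2_fc_range = log2_fc_range,
              replicate_sd = replicate_sd,
              n_replicates = as.integer(n_replicates),
              noise_floor = noise_floor,
              low_signal_fraction = low_signal_fraction,
              phospho_fraction = phospho_fraction,
              sites_per_protein = as.integer(sites_per_protein),
              detection_prob = detection_prob,
              n_template_edges = as.integer(n_template_edges),
              protein_length = as.integer(protein_length))
  for (f in c("ortholog_fraction", "divergence", "de_fraction",
              "low_signal_fraction", "phospho_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop_("'", f, "' must be in [0, 1]")
  if (cfg$n_replicates < 2L) stop_("need at least 2 replicates")
  if (any(cfg$detection_prob < 0 | cfg$detection_prob > 1))
    stop_("detection probabilities must be in [0, 1]")
  if (diff(cfg$protein_length) < 0 || cfg$protein_length[1L] < 30L)
    stop_("'protein_length' must be an increasing range with min >= 30")
  if (cfg$sites_per_protein[1L] < 1L)
    stop_("at least one site per phosphoprotein")
  structure(cfg, class = "sim_config")
}

random_protein <- function(len) {
  paste(sample(names(aa_background), len, replace = TRUE,
               prob = aa_background), collapse = "")
}

mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit)
    chars[i] <- sample(setdiff(names(aa_background), chars[i]), 1L)
  paste(chars, collapse = "")
}

# tryptic fragments: cut after K/R not followed by P; returns start/end
digest_tryptic <- function(seq) {
  chars <- strsplit(seq, "")[[1L]]
  n <- length(chars)
  cuts <- which(chars %in% c("K", "R") & c(chars[-1L], "") != "P" &
                  seq_len(n) < n)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  data.frame(start = starts, end = ends)
}

# internal K/R (not before P) within a peptide = missed cleavages
count_missed_cleavages <- function(peptide) {
  chars <- strsplit(toupper(peptide), "")[[1L]]
  n <- length(chars)
  if (n < 2L) return(0L)
  sum(chars[-n] %in% c("K", "R") & chars[-1L] != "P")
}

#' Generate a full synthetic dataset with planted truth
#'
#' Produces every pipeline input: a signal-thresholdable abundance matrix
#' with planted condition shifts and log-normal replicate noise, a
#' phosphopeptide table whose rows are genuine tryptic fragments of the
#' query proteome with lowercase phospho-marks, a template/query proteome
#' pair with planted 1:1 orthologs at the configured divergence, a
#' bait->prey template edge list, a pathway annotation, and the
#' `truth` record enumerating everything that was planted. Fully
#' reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List of class `"sim_dataset"` with elements `abundance`,
#'   `phosphopeptides`, `proteome_query`, `proteome_template`,
#'   `template_edges`, `pathway_annotation`, `truth`, `config`.
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  run_id <- sprintf("sim-%d", cfg$seed)

  # -- sequences ---------------------------------------------------------
  set.seed(sub_seed(cfg$seed, 1L))
  t_acc <- sprintf("T%04d", seq_len(cfg$n_template_proteins))
  t_len <- sample(cfg$protein_length[1L]:cfg$protein_length[2L],
                  cfg$n_template_proteins, replace = TRUE)
  template <- stats::setNames(vapply(t_len, random_protein, ""), t_acc)
  q_acc <- sprintf("Q%04d", seq_len(cfg$n_proteins))
  n_orth <- round(cfg$ortholog_fraction *
                    min(cfg$n_proteins, cfg$n_template_proteins))
  query <- character(cfg$n_proteins)
  for (i in seq_len(cfg$n_proteins)) {
    query[i] <- if (i <= n_orth) mutate_protein(template[[i]], cfg$divergence)
                else random_protein(sample(cfg$protein_length[1L]:
                                             cfg$protein_length[2L], 1L))
  }
  names(query) <- q_acc
  ortholog_pairs <- data.frame(template = t_acc[seq_len(n_orth)],
                               query = q_acc[seq_len(n_orth)],
                               stringsAsFactors = FALSE)

  # -- planted phosphosites (mutates query residues to S/T/Y) ------------
  set.seed(sub_seed(cfg$seed, 2L))
  n_phos <- round(cfg$phospho_fraction * cfg$n_proteins)
  phos_acc <- sort(sample(q_acc, n_phos))
  site_rows <- list(); pep_rows <- list()
  for (a in phos_acc) {
    chars <- strsplit(query[[a]], "")[[1L]]
    len <- length(chars)
    k <- sample(cfg$sites_per_protein[1L]:cfg$sites_per_protein[2L], 1L)
    if (len - 20L < k) stop_("protein too short for requested sites: ", a)
    pos <- sort(sample(seq(10L, len - 10L), k))
    res <- sample(c("S", "T", "Y"), k, replace = TRUE)
    chars[pos] <- res
    # keep flanks of each site non-cleaving so the fragment is stable
    query[[a]] <- paste(chars, collapse = "")
    frags <- digest_tryptic(query[[a]])
    for (j in seq_len(k)) {
      fi <- which(frags$start <= pos[j] & frags$end >= pos[j])[1L]
      s <- frags$start[fi]; e <- frags$end[fi]
      if (stats::runif(1L) < 0.3 && fi < nrow(frags)) e <- frags$end[fi + 1L]
      pep <- chars[s:e]
      pep[pos[j] - s + 1L] <- tolower(res[j])
      det <- stats::runif(3L) < cfg$detection_prob
      if (!any(det)) det[2L] <- TRUE  # at least one condition
      pep_rows[[length(pep_rows) + 1L]] <- data.frame(
        accession = a, peptide = paste(pep, collapse = ""),
        site_labels = paste0(res[j], pos[j], tolower(res[j])),
        cond_low = as.integer(det[1L]), cond_opt = as.integer(det[2L]),
        cond_high = as.integer(det[3L]),
        precursor_ppm = round(stats::runif(1L, 1, 20), 1),
        product_ppm = round(stats::runif(1L, 5, 50), 1),
        missed_cleavages = NA_integer_, stringsAsFactors = FALSE)
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        accession = a, residue = res[j], position = pos[j],
        LOW = det[1L], OPT = det[2L], HIGH = det[3L],
        stringsAsFactors = FALSE)
    }
  }
  peptides <- do.call(rbind, pep_rows) %||% data.frame(
    accession = character(), peptide = character(),
    site_labels = character(), cond_low = integer(), cond_opt = integer(),
    cond_high = integer(), precursor_ppm = numeric(),
    product_ppm = numeric(), missed_cleavages = integer())
  if (nrow(peptides)) {
    peptides$missed_cleavages <-
      vapply(peptides$peptide, count_missed_cleavages, 0L, USE.NAMES = FALSE)
    drop <- peptides$missed_cleavages > 2L  # rare long merges; keep <= 2
    if (any(drop)) {
      peptides <- peptides[!drop, , drop = FALSE]
      site_rows <- site_rows[!drop]
    }
  }
  phospho_sites <- do.call(rbind, site_rows) %||%
    data.frame(accession = character(), residue = character(),
               position = integer())
  peptides <- validate_phosphopeptides(peptides)

  # -- abundances --------------------------------------------------------
  set.seed(sub_seed(cfg$seed, 3L))
  nrep <- cfg$n_replicates
  condition <- rep(conditions(), each = nrep)
  replicate <- rep(seq_len(nrep), times = 3L)
  baseline <- stats::runif(cfg$n_proteins, 15, 19)
  de <- list()
  shift <- matrix(0, cfg$n_proteins, 3L,
                  dimnames = list(q_acc, conditions()))
  n_de <- round(cfg$de_fraction * cfg$n_proteins)
  for (stress in c("LOW", "HIGH")) {
    idx <- sample(cfg$n_proteins, n_de)
    l2 <- sample(c(-1, 1), n_de, replace = TRUE) *
      stats::runif(n_de, cfg$log2_fc_range[1L], cfg$log2_fc_range[2L])
    shift[idx, stress] <- l2
    de[[stress]] <- data.frame(accession = q_acc[idx],
                               contrast = paste0(stress, "_vs_OPT"),
                               log2_fc = l2, stringsAsFactors = FALSE)
  }
  log2int <- matrix(rep(baseline, 3L * nrep), cfg$n_proteins) +
    shift[, rep(match(condition, conditions()), 1L)] +
    stats::rnorm(cfg$n_proteins * 3L * nrep, 0, cfg$replicate_sd)
  intensity <- 2^log2int
  dimnames(intensity) <- list(q_acc, paste0(condition, ".", replicate))
  n_low <- floor(cfg$low_signal_fraction * length(intensity))
  low_idx <- if (n_low > 0L) sample(length(intensity), n_low) else integer()
  intensity[low_idx] <- stats::runif(n_low, 0.1, 2.9) * cfg$noise_floor
  abundance <- abundance_matrix(intensity, rep(cfg$noise_floor,
                                               length(condition)),
                                condition, replicate)

  # -- template network and annotation -----------------------------------
  set.seed(sub_seed(cfg$seed, 4L))
  possible <- cfg$n_template_proteins * (cfg$n_template_proteins - 1L)
  n_edge <- min(cfg$n_template_edges, possible)
  pick <- sample(possible, n_edge)
  bait <- t_acc[(pick - 1L) %/% (cfg$n_template_proteins - 1L) + 1L]
  rest <- (pick - 1L) %% (cfg$n_template_proteins - 1L) + 1L
  prey <- t_acc[ifelse(rest >= match(bait, t_acc), rest + 1L, rest)]
  template_edges <- data.frame(bait = bait, prey = prey,
                               evidence = "synthetic-Y2H",
                               stringsAsFactors = FALSE)
  pathways <- c("Nitrogen metabolism", "Photosynthesis",
                "Carbon fixation in photosynthetic organisms",
                "Oxidative phosphorylation", "Ribosome",
                "Biosynthesis of amino acids", "Purine metabolism",
                "Two-component system")
  ann_acc <- sort(sample(q_acc, round(0.5 * cfg$n_proteins)))
  annotation <- do.call(rbind, lapply(ann_acc, function(a)
    data.frame(accession = a,
               pathway = sample(pathways, sample(1:2, 1L)),
               stringsAsFactors = FALSE)))

  # -- truth -------------------------------------------------------------
  de_all <- rbind(de$LOW, de$HIGH)
  max_fc <- tapply(abs(de_all$log2_fc), de_all$accession, max)
  expected_bilevel <- sort(intersect(
    names(max_fc)[max_fc >= log2(1.5)], unique(phospho_sites$accession)))
  truth <- list(run_id = run_id, de_proteins = de_all,
                phospho_sites = phospho_sites,
                ortholog_pairs = ortholog_pairs,
                template_edges = template_edges,
                expected_bilevel = expected_bilevel,
                low_signal_cells = low_idx)
  structure(list(abundance = abundance, phosphopeptides = peptides,
                 proteome_query = query, proteome_template = template,
                 template_edges = template_edges,
                 pathway_annotation = annotation, truth = truth,
                 config = cfg, run_id = run_id),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset %s: %d query / %d template proteins, %d phosphopeptide rows, %d template edges\n",
              x$run_id, length(x$proteome_query), length(x$proteome_template),
              nrow(x$phosphopeptides), nrow(x$template_edges)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits all input files in the pipeline's TSV/FASTA dialects plus
#' `truth.json`.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(abundance = file.path(dir, "abundance.tsv"),
             phosphopeptides = file.path(dir, "phosphopeptides.tsv"),
             proteome_query = file.path(dir, "proteome_query.fasta"),
             proteome_template = file.path(dir, "proteome_template.fasta"),
             template_edges = file.path(dir, "template_edges.tsv"),
             pathway_annotation = file.path(dir, "pathways.tsv"),
             truth = file.path(dir, "truth.json"))
  write_abundance(dataset$abundance, paths["abundance"])
  write_tsv(dataset$phosphopeptides, paths["phosphopeptides"])
  write_fasta(dataset$proteome_query, paths["proteome_query"])
  write_fasta(dataset$proteome_template, paths["proteome_template"])
  write_tsv(dataset$template_edges, paths["template_edges"])
  write_tsv(dataset$pathway_annotation, paths["pathway_annotation"])
  tr <- dataset$truth
  tr$low_signal_cells <- NULL
  jsonlite::write_json(tr, paths["truth"], auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(paths)
}

rate <- function(num, den) if (den > 0L) num / den else 0

#' Evaluate pipeline recovery against planted truth
#'
#' Per-stage confusion counts comparing pipeline outputs with what the
#' generator planted. All components of `results` are optional; stages
#' without output report zero counts.
#'
#' @param truth The `truth` element of a [generate_dataset()] result.
#' @param results Named list with any of: `expression` (row-bound
#'   `"expression_results"` of both contrasts), `inventories`
#'   (from [aggregate_all_sites()]), `rbh` (from
#'   [reciprocal_best_hits()] query-vs-template), `network` (a
#'   `"ppi_network"` on the query species), `report` (a
#'   `"bilevel_report"`), and optionally `run_id`.
#' @return List of class `"recovery_report"` with per-stage sensitivities,
#'   precisions and counts. For differential expression both the full-call
#'   sensitivity (direction, significance and fold-change cut-off all
#'   recovered) and the significance-only sensitivity (correct direction
#'   at p below the cut-off, ignoring the fold-change threshold) are
#'   reported, together with the false-call rate on null proteins and the
#'   mean absolute log2 fold-change error on planted proteins.
#' @export
evaluate_recovery <- function(truth, results) {
  if (!is.null(results$run_id) && !is.null(truth$run_id) &&
      !identical(results$run_id, truth$run_id))
    stop_("results were produced from dataset '", results$run_id,
          "' but truth is from '", truth$run_id, "'")
  out <- list()

  expr <- results$expression
  if (!is.null(expr)) {
    de <- truth$de_proteins
    key_t <- paste(de$accession, de$contrast)
    key_e <- paste(expr$accession, expr$contrast)
    m <- match(key_t, key_e)
    planted_dir <- ifelse(de$log2_fc > 0, "UP", "DOWN")
    call <- expr$call[m]
    called_ok <- !is.na(call) & call == planted_dir
    sig_ok <- !is.na(m) & !is.na(expr$p_value[m]) &
      expr$p_value[m] <= 0.05 &
      sign(expr$log2_fc[m]) == sign(de$log2_fc)
    null_rows <- !(key_e %in% key_t) & expr$call != "UNTESTABLE"
    fc_err <- abs(expr$log2_fc[m] - de$log2_fc)
    out$de <- list(
      n_planted = nrow(de),
      call_sensitivity = rate(sum(called_ok), nrow(de)),
      significance_sensitivity = rate(sum(sig_ok), nrow(de)),
      false_call_rate = rate(sum(expr$call[null_rows] %in% c("UP", "DOWN")),
                             sum(null_rows)),
      mean_abs_log2fc_error = if (any(!is.na(fc_err)))
        mean(fc_err, na.rm = TRUE) else 0)
  }

  inv <- results$inventories
  if (!is.null(inv)) {
    det <- sites_table(inv)
    key_d <- if (is.null(det)) character() else
      paste(det$accession, det$residue, det$position)
    key_p <- paste(truth$phospho_sites$accession,
                   truth$phospho_sites$residue,
                   truth$phospho_sites$position)
    out$phospho <- list(
      n_planted = length(unique(key_p)),
      sensitivity = rate(sum(unique(key_p) %in% key_d),
                         length(unique(key_p))),
      precision = rate(sum(unique(key_d) %in% key_p),
                       length(unique(key_d))))
  }

  rbh <- results$rbh
  if (!is.null(rbh)) {
    found <- paste(rbh$query_a, rbh$subject_b)
    planted <- paste(truth$ortholog_pairs$query,
                     truth$ortholog_pairs$template)
    out$orthology <- list(
      n_planted = length(planted),
      recall = rate(sum(planted %in% found), length(planted)),
      precision = rate(sum(found %in% planted), length(found)))
  }

  net <- results$network
  if (!is.null(net)) {
    map <- stats::setNames(truth$ortholog_pairs$query,
                           truth$ortholog_pairs$template)
    te <- truth$template_edges
    mapped <- te$bait %in% names(map) & te$prey %in% names(map)
    expected <- unique(paste(map[te$bait[mapped]], map[te$prey[mapped]]))
    got <- paste(net$edges$source, net$edges$target)
    out$network <- list(
      n_expected = length(expected),
      completeness = rate(sum(expected %in% got), length(expected)),
      soundness = rate(sum(unique(got) %in% expected),
                       length(unique(got))))
  }

  rep <- results$report
  if (!is.null(rep)) {
    out$bilevel <- list(
      n_expected = length(truth$expected_bilevel),
      coverage = rate(sum(truth$expected_bilevel %in% rep$rows$accession),
                      length(truth$expected_bilevel)))
  }
  structure(out, class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery against planted truth\n")
  for (nm in names(x)) {
    v <- unlist(x[[nm]])
    cat(sprintf("  %-9s %s\n", nm,
                paste(names(v), signif(v, 3), sep = "=", collapse = "  ")))
  }
  invisible(x)
}
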