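# Phosphopeptide evidence: lowercase s/t/y in the peptide string marks a
# phosphorylated residue; site labels such as "T234t" give the residue and
# its 1-based position in the protein.

parse_site_labels <- function(labels) {
  if (length(labels) == 1L && is.character(labels))
    labels <- strsplit(trimws(labels), "[[:space:]]+")[[1L]]
  labels <- labels[nzchar(labels)]
  if (!length(labels))
    return(data.frame(residue = character(), position = integer()))
  m <- regmatches(labels, regexec("^([STY])([0-9]+)([sty])$", labels))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop_("unparseable site label(s): ", paste(labels[bad], collapse = ", "))
  res <- vapply(m, `[`, "", 2L)
  low <- vapply(m, `[`, "", 4L)
  if (any(tolower(res) != low))
    stop_("site label residue letters disagree: ",
          paste(labels[tolower(res) != low], collapse = ", "))
  data.frame(residue = res,
             position = as.integer(vapply(m, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' Parse one phosphopeptide record
#'
#' Cross-validates the lowercase phospho-marks in the peptide string
#' against the site labels: the number of lowercase s/t/y letters must
#' equal the number of labels, and the residue identity of each lowercase
#' letter (in peptide order) must match the corresponding label's residue.
#' Positions in the labels are 1-based protein coordinates and are not
#' checked against the peptide (peptide start positions are not part of
#' the evidence).
#'
#' @param accession Protein accession.
#' @param peptide Amino-acid string; lowercase `s`/`t`/`y` marks
#'   phosphorylated residues.
#' @param site_labels Labels like `"T234t"`, as a character vector or one
#'   space-separated string.
#' @param conditions_detected Subset of [conditions()] in which the
#'   peptide was detected.
#' @param precursor_tol_ppm,product_tol_ppm Mass-tolerance metadata of the
#'   identification (ppm).
#' @param missed_cleavages Number of missed tryptic cleavages (<= 2).
#' @return An object of class `"phosphopeptide"`: a list with the
#'   validated fields and a `sites` data frame (`residue`, `position`).
#' @examples
#' parse_phosphopeptide("P1", "TIVyKGMVRSAVLGEFYR", "Y237y", "OPT")
#' @export
parse_phosphopeptide <- function(accession, peptide, site_labels,
                                 conditions_detected = character(),
                                 precursor_tol_ppm = NA_real_,
                                 product_tol_ppm = NA_real_,
                                 missed_cleavages = NA_integer_) {
  if (!nzchar(peptide)) stop_("empty peptide string")
  if (grepl("[^A-Za-z]", peptide)) stop_("peptide contains non-letter characters")
  sites <- parse_site_labels(site_labels)
  marks <- regmatches(peptide, gregexpr("[sty]", peptide))[[1L]]
  if (length(marks) != nrow(sites))
    stop_(sprintf("peptide '%s': %d lowercase phospho-mark(s) but %d site label(s)",
                  peptide, length(marks), nrow(sites)))
  if (nrow(sites) && any(toupper(marks) != sites$residue))
    stop_(sprintf("peptide '%s': lowercase residues (%s) do not match labels (%s)",
                  peptide, paste(toupper(marks), collapse = ""),
                  paste(sites$residue, collapse = "")))
  if (!all(conditions_detected %in% conditions()))
    stop_("conditions must be among: ", paste(conditions(), collapse = ", "))
  if (!is.na(missed_cleavages) && missed_cleavages > 2L)
    stop_("missed_cleavages must be <= 2")
  structure(list(accession = accession, peptide = peptide, sites = sites,
                 conditions_detected = unique(conditions_detected),
                 precursor_tol_ppm = as.numeric(precursor_tol_ppm),
                 product_tol_ppm = as.numeric(product_tol_ppm),
                 missed_cleavages = as.integer(missed_cleavages)),
            class = "phosphopeptide")
}

#' @export
print.phosphopeptide <- function(x, ...) {
  cat(sprintf("%s  %s  [%s]  detected: %s\n", x$accession, x$peptide,
              paste0(x$sites$residue, x$sites$position, collapse = " "),
              paste(x$conditions_detected, collapse = ",") %||% ""))
  invisible(x)
}

# serialize a parsed phosphopeptide back to the TSV dialect row
format_phosphopeptide <- function(pp) {
  data.frame(accession = pp$accession, peptide = pp$peptide,
             site_labels = paste0(pp$sites$residue, pp$sites$position,
                                  tolower(pp$sites$residue), collapse = " "),
             cond_low = as.integer("LOW" %in% pp$conditions_detected),
             cond_opt = as.integer("OPT" %in% pp$conditions_detected),
             cond_high = as.integer("HIGH" %in% pp$conditions_detected),
             precursor_ppm = pp$precursor_tol_ppm,
             product_ppm = pp$product_tol_ppm,
             missed_cleavages = pp$missed_cleavages,
             stringsAsFactors = FALSE)
}

#' Read a phosphopeptide evidence TSV
#'
#' Dialect: columns `accession`, `peptide`, `site_labels` (space
#' separated), `cond_low`, `cond_opt`, `cond_high` (0/1),
#' `precursor_ppm`, `product_ppm`, `missed_cleavages`. Every row is
#' validated through [parse_phosphopeptide()].
#'
#' @param path Path to the TSV file.
#' @param on_error `"stop"` (default) aborts naming the offending rows;
#'   `"drop"` removes them with a warning.
#' @return The validated data frame (class `"phosphopeptide_table"`).
#' @export
read_phosphopeptides <- function(path, on_error = c("stop", "drop")) {
  on_error <- match.arg(on_error)
  df <- read_tsv(path)
  validate_phosphopeptides(df, on_error = on_error)
}

#' Validate a phosphopeptide table
#'
#' @param df Data frame in the dialect of [read_phosphopeptides()].
#' @param on_error `"stop"` or `"drop"`.
#' @return The validated data frame (class `"phosphopeptide_table"`).
#' @export
validate_phosphopeptides <- function(df, on_error = c("stop", "drop")) {
  on_error <- match.arg(on_error)
  need <- c("accession", "peptide", "site_labels", "cond_low", "cond_opt",
            "cond_high", "precursor_ppm", "product_ppm", "missed_cleavages")
  if (!all(need %in% names(df)))
    stop_("phosphopeptide table needs columns: ", paste(need, collapse = ", "))
  errs <- character()
  for (i in seq_len(nrow(df))) {
    e <- tryCatch({
      parse_phosphopeptide(df$accession[i], df$peptide[i], df$site_labels[i],
                           conditions()[c(df$cond_low[i], df$cond_opt[i],
                                          df$cond_high[i]) == 1],
                           df$precursor_ppm[i], df$product_ppm[i],
                           df$missed_cleavages[i])
      NA_character_
    }, error = function(err) conditionMessage(err))
    if (!is.na(e)) errs[as.character(i)] <- e
  }
  if (length(errs)) {
    msg <- paste0("row ", names(errs), ": ", errs, collapse = "\n  ")
    if (on_error == "stop") stop_("rejected phosphopeptide rows:\n  ", msg)
    warning("dropped ", length(errs), " phosphopeptide row(s):\n  ", msg,
            call. = FALSE)
    df <- df[-as.integer(names(errs)), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("phosphopeptide_table", "data.frame")
  df
}

#' Filter phosphopeptides by stringency tier
#'
#' High stringency keeps records with |precursor tolerance| <= 20 ppm and
#' |product tolerance| <= 50 ppm; low stringency keeps <= 50 / <= 100 ppm.
#' The high-stringency result is always a subset of the low-stringency
#' one. Records with missing tolerances are excluded with a warning.
#'
#' @param df A phosphopeptide table (see [read_phosphopeptides()]).
#' @param tier `"HIGH"` (default) or `"LOW"`.
#' @return The filtered table.
#' @export
filter_stringency <- function(df, tier = c("HIGH", "LOW")) {
  tier <- match.arg(tier)
  lim <- if (tier == "HIGH") c(20, 50) else c(50, 100)
  miss <- is.na(df$precursor_ppm) | is.na(df$product_ppm)
  if (any(miss))
    warning(sum(miss), " record(s) without tolerance metadata excluded",
            call. = FALSE)
  keep <- !miss & abs(df$precursor_ppm) <= lim[1] & abs(df$product_ppm) <= lim[2]
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate phosphosite evidence for one protein
#'
#' Deduplicates sites by (residue, position) taking the union of detection
#' conditions, counts peptides (rows) and unique phosphopeptides (exact
#' case-sensitive modified strings), and tallies pS/pT/pY.
#'
#' @param df Phosphopeptide table rows, all sharing one accession.
#' @return Object of class `"site_inventory"`: list with `accession`,
#'   `n_phosphopeptides`, `n_unique_phosphopeptides`, `counts` (named
#'   pS/pT/pY/total) and `sites` (data frame `residue`, `position`,
#'   `LOW`, `OPT`, `HIGH`), sites ordered by position.
#' @examples
#' tab <- data.frame(
#'   accession = "GS", peptide = c("tIVYKGMVR", "TIVyKGMVR"),
#'   site_labels = c("T234t", "Y237y"),
#'   cond_low = c(1, 1), cond_opt = c(1, 1), cond_high = c(0, 1),
#'   precursor_ppm = 20, product_ppm = 50, missed_cleavages = 1)
#' aggregate_sites(tab)$counts  # pS 0, pT 1, pY 1, total 2
#' @export
aggregate_sites <- function(df) {
  if (nrow(df) == 0L) {
    inv <- list(accession = NA_character_, n_phosphopeptides = 0L,
                n_unique_phosphopeptides = 0L,
                counts = c(pS = 0L, pT = 0L, pY = 0L, total = 0L),
                sites = data.frame(residue = character(),
                                   position = integer(), LOW = logical(),
                                   OPT = logical(), HIGH = logical()))
    return(structure(inv, class = "site_inventory"))
  }
  if (length(unique(df$accession)) != 1L)
    stop_("aggregate_sites() expects rows of a single accession")
  pieces <- lapply(seq_len(nrow(df)), function(i) {
    s <- parse_site_labels(df$site_labels[i])
    if (!nrow(s)) return(NULL)
    s$LOW <- df$cond_low[i] == 1
    s$OPT <- df$cond_opt[i] == 1
    s$HIGH <- df$cond_high[i] == 1
    s
  })
  all_sites <- do.call(rbind, pieces)
  key <- paste(all_sites$residue, all_sites$position)
  sites <- do.call(rbind, lapply(split(all_sites, key), function(g) {
    data.frame(residue = g$residue[1L], position = g$position[1L],
               LOW = any(g$LOW), OPT = any(g$OPT), HIGH = any(g$HIGH),
               stringsAsFactors = FALSE)
  }))
  sites <- sites[order(sites$position, sites$residue), , drop = FALSE]
  rownames(sites) <- NULL
  counts <- c(pS = sum(sites$residue == "S"), pT = sum(sites$residue == "T"),
              pY = sum(sites$residue == "Y"))
  counts <- c(counts, total = sum(counts))
  structure(list(accession = df$accession[1L],
                 n_phosphopeptides = nrow(df),
                 n_unique_phosphopeptides = length(unique(df$peptide)),
                 counts = counts, sites = sites),
            class = "site_inventory")
}

#' @export
print.site_inventory <- function(x, ...) {
  cat(sprintf("%s: %d peptide(s), %d unique; sites pS=%d pT=%d pY=%d (total %d)\n",
              x$accession, x$n_phosphopeptides, x$n_unique_phosphopeptides,
              x$counts["pS"], x$counts["pT"], x$counts["pY"],
              x$counts["total"]))
  if (nrow(x$sites)) {
    lab <- paste0("p", x$sites$residue, x$sites$position)
    cat(" ", paste(lab, collapse = " "), "\n")
  }
  invisible(x)
}

#' Aggregate site inventories for every protein in a table
#'
#' @param df A phosphopeptide table.
#' @return Named list of [aggregate_sites()] inventories, ordered by
#'   accession.
#' @export
aggregate_all_sites <- function(df) {
  accs <- sort(unique(df$accession))
  stats::setNames(lapply(accs, function(a)
    aggregate_sites(df[df$accession == a, , drop = FALSE])), accs)
}

# flatten inventories to one site table: accession, residue, position, conds
sites_table <- function(inventories) {
  do.call(rbind, lapply(inventories, function(inv) {
    if (!nrow(inv$sites)) return(NULL)
    cbind(accession = inv$accession, inv$sites, stringsAsFactors = FALSE)
  }))
}

#' Phosphosite type ratio
#'
#' Percentage of distinct phosphosites on serine, threonine and tyrosine,
#' rounded to one decimal.
#'
#' @param x Either a data frame with a `residue` column (one row per
#'   distinct site, e.g. from [read_site_list()]), or a list of
#'   [aggregate_sites()] inventories.
#' @return Named numeric vector `c(pct_S, pct_T, pct_Y)`.
#' @examples
#' site_type_ratio(data.frame(residue = c("S", "S", "T", "Y")))
#' @export
site_type_ratio <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- sites_table(x)
  if (is.null(x) || nrow(x) == 0L) stop_("no phosphosites supplied")
  if (!all(x$residue %in% c("S", "T", "Y")))
    stop_("residues must be S, T or Y")
  n <- nrow(x)
  round(c(pct_S = 100 * sum(x$residue == "S") / n,
          pct_T = 100 * sum(x$residue == "T") / n,
          pct_Y = 100 * sum(x$residue == "Y") / n), 1)
}

#' Read a phosphosite list
#'
#' Loader for external site lists (e.g. a published supplementary table of
#' high-stringency sites): a TSV with columns `accession`, `residue`
#' (S/T/Y) and `position`. When the file is absent the function degrades
#' gracefully, returning `NULL` with a message, so that optional external
#' checks can be bypassed without failing.
#'
#' @param path Path to the TSV file.
#' @return Data frame of distinct sites, or `NULL` when `path` does not
#'   exist.
#' @export
read_site_list <- function(path) {
  if (!file.exists(path)) {
    message("site list not available: ", path)
    return(NULL)
  }
  df <- read_tsv(path)
  need <- c("accession", "residue", "position")
  if (!all(need %in% names(df)))
    stop_("site list needs columns: ", paste(need, collapse = ", "))
  df <- unique(df[need])
  rownames(df) <- NULL
  df
}
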