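# Cross-species orthology: local-alignment similarity with a
# Karlin-Altschul e-value, reciprocal best hits, Markov clustering of the
# similarity graph, and domain-architecture confirmation.

# Published ungapped Karlin-Altschul parameters per substitution matrix.
ka_constants <- list(BLOSUM62 = c(lambda = 0.3176, K = 0.134))

get_submat <- function(matrix_name) {
  if (is.matrix(matrix_name)) return(matrix_name)
  e <- new.env()
  utils::data(list = matrix_name, package = "Biostrings", envir = e)
  get(matrix_name, envir = e)
}

validate_residues <- function(seq, allowed, label) {
  chars <- strsplit(seq, "")[[1L]]
  bad <- which(!chars %in% allowed)
  if (length(bad))
    stop_(sprintf("invalid residue '%s' at position %d of %s",
                  chars[bad[1L]], bad[1L], label))
  invisible(TRUE)
}

#' Local alignment similarity with an e-value
#'
#' Smith-Waterman local alignment with affine gap penalties (a length-g
#' gap costs `gap_open + g * gap_extend`; the score of the empty alignment
#' is 0), scored with a substitution matrix, plus a BLAST-style
#' Karlin-Altschul statistic: `bits = (lambda * S - ln K) / ln 2` and
#' `E = search_space * 2^-bits`, using the published ungapped constants
#' for the matrix.
#'
#' @param seq_a,seq_b Amino-acid strings.
#' @param matrix Substitution matrix name (default `"BLOSUM62"`) or an
#'   actual matrix (then `lambda`/`K` must be supplied).
#' @param gap_open,gap_extend Affine gap penalties (positive costs);
#'   defaults 11 and 1.
#' @param search_space Product m x n used in the e-value; defaults to
#'   `nchar(seq_a) * nchar(seq_b)`.
#' @param lambda,K Karlin-Altschul constants; default to the published
#'   values for the named matrix.
#' @return Object of class `"similarity_hit"`: list with `raw_score`,
#'   `bit_score`, `evalue`.
#' @examples
#' align_score("HEAGAWGHEE", "PAWHEAE")$raw_score
#' @export
align_score <- function(seq_a, seq_b, matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1,
                        search_space = NULL, lambda = NULL, K = NULL) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop_("sequences must be non-empty")
  mat <- get_submat(matrix)
  allowed <- rownames(mat)
  validate_residues(seq_a, allowed, "seq_a")
  validate_residues(seq_b, allowed, "seq_b")
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "local", scoreOnly = TRUE)
  s <- max(0, s)
  search_space <- search_space %||% (nchar(seq_a) * nchar(seq_b))
  hit <- ka_hit(s, search_space, matrix, lambda, K)
  structure(c(list(query = NA_character_, subject = NA_character_), hit),
            class = "similarity_hit")
}

# bit score and e-value from a raw score
ka_hit <- function(raw_score, search_space, matrix = "BLOSUM62",
                   lambda = NULL, K = NULL) {
  if (is.null(lambda) || is.null(K)) {
    nm <- if (is.character(matrix)) matrix else ""
    kc <- ka_constants[[nm]]
    if (is.null(kc))
      stop_("no published Karlin-Altschul constants for matrix '", nm,
            "'; supply lambda and K")
    lambda <- lambda %||% kc[["lambda"]]
    K <- K %||% kc[["K"]]
  }
  bits <- (lambda * raw_score - log(K)) / log(2)
  list(raw_score = raw_score, bit_score = bits,
       evalue = search_space * 2^(-bits))
}

#' @export
print.similarity_hit <- function(x, ...) {
  cat(sprintf("raw score %g, bit score %.1f, e-value %.3g\n",
              x$raw_score, x$bit_score, x$evalue))
  invisible(x)
}

# coerce a proteome argument (path, AAStringSet, named character) to a
# named character vector of sequences
as_proteome <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- Biostrings::readAAStringSet(x)
  if (methods::is(x, "AAStringSet")) {
    nm <- sub("\\s.*$", "", names(x))
    x <- stats::setNames(as.character(x), nm)
  }
  if (!is.character(x) || is.null(names(x)) || anyDuplicated(names(x)))
    stop_("proteome must be a FASTA path, AAStringSet, or uniquely named character vector")
  x
}

#' Write a proteome FASTA
#'
#' @param seqs Named character vector of amino-acid sequences.
#' @param path Output file (a `.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

# all-vs-all raw local-alignment score matrix (rows = a, cols = b),
# vectorised over patterns per subject
score_matrix <- function(a, b, matrix = "BLOSUM62", gap_open = 11,
                         gap_extend = 1) {
  mat <- get_submat(matrix)
  aset <- Biostrings::AAStringSet(a)
  out <- matrix(0, length(a), length(b), dimnames = list(names(a), names(b)))
  for (j in seq_along(b)) {
    sc <- Biostrings::pairwiseAlignment(
      aset, Biostrings::AAString(b[[j]]), substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend,
      type = "local", scoreOnly = TRUE)
    out[, j] <- pmax(0, sc)
  }
  out
}

#' Reciprocal best hits between two proteomes
#'
#' All-vs-all local alignment; the pair (a, b) is an ortholog pair when b
#' is a's highest-scoring hit, a is b's highest-scoring hit, and both
#' e-values are strictly below `thr$rbh_evalue`. Score ties are broken by
#' the lexicographically smallest subject accession, making the result
#' deterministic.
#'
#' @param proteome_a,proteome_b FASTA path, `AAStringSet`, or named
#'   character vector.
#' @param thr A [thresholds()] object (`rbh_evalue` is used).
#' @param matrix,gap_open,gap_extend Alignment parameters as in
#'   [align_score()].
#' @return Data frame with `query_a`, `subject_b`, `raw_score`,
#'   `evalue_ab`, `evalue_ba`, ordered by `query_a`.
#' @export
reciprocal_best_hits <- function(proteome_a, proteome_b, thr = thresholds(),
                                 matrix = "BLOSUM62", gap_open = 11,
                                 gap_extend = 1) {
  a <- as_proteome(proteome_a)
  b <- as_proteome(proteome_b)
  if (!length(a) || !length(b)) stop_("both proteomes must be non-empty")
  sc <- score_matrix(a, b, matrix, gap_open, gap_extend)
  best_of <- function(scores, names_sorted) {
    # index of max score; ties -> lexicographically smallest name
    cand <- which(scores == max(scores))
    cand[order(names_sorted[cand])][1L]
  }
  rows <- list()
  ord_b <- colnames(sc); ord_a <- rownames(sc)
  for (i in seq_along(a)) {
    j <- best_of(sc[i, ], ord_b)
    if (best_of(sc[, j], ord_a) != i) next
    ea <- ka_hit(sc[i, j], nchar(a[[i]]) * nchar(b[[j]]), matrix)$evalue
    if (!(ea < thr$rbh_evalue)) next  # strict; symmetric search space
    rows[[length(rows) + 1L]] <- data.frame(
      query_a = names(a)[i], subject_b = names(b)[j],
      raw_score = sc[i, j], evalue_ab = ea, evalue_ba = ea,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_a = character(), subject_b = character(),
               raw_score = numeric(), evalue_ab = numeric(),
               evalue_ba = numeric())
  out <- out[order(out$query_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Similarity graph from reciprocal/all-vs-all hits
#'
#' Convenience: turns an RBH table into the weighted, undirected edge list
#' consumed by [markov_cluster()], with weights `-log10(evalue)` (capped
#' at 300 for zero e-values).
#'
#' @param hits Data frame with `query_a`, `subject_b`, `evalue_ab`.
#' @return Data frame `from`, `to`, `weight`.
#' @export
similarity_graph <- function(hits) {
  w <- -log10(pmax(hits$evalue_ab, 1e-300))
  data.frame(from = hits$query_a, to = hits$subject_b, weight = w,
             stringsAsFactors = FALSE)
}

#' Markov clustering of a similarity graph
#'
#' Classic MCL: the symmetric weighted adjacency matrix (self-loops set to
#' the maximum incident weight of each node) is column-normalised and then
#' alternately squared (expansion) and taken to the `inflation` power
#' column-wise (inflation), pruning entries below `tol`, until the matrix
#' is stable. Clusters are the connected components of the non-zero
#' support of the limit matrix; every node is assigned exactly once.
#'
#' @param graph Data frame `from`, `to`, `weight` (weights > 0), or a
#'   square named adjacency matrix.
#' @param inflation Inflation exponent, default 1.5.
#' @param max_iter Iteration cap, default 100; non-convergence returns the
#'   current partition with `converged = FALSE` and a warning.
#' @param tol Pruning / convergence tolerance, default 1e-6.
#' @param nodes Optional full node set (to include isolated nodes).
#' @return Object of class `"mcl_partition"`: list with `groups` (list of
#'   sorted member vectors, ordered by smallest member), `converged`,
#'   `n_iter`.
#' @export
markov_cluster <- function(graph, inflation = 1.5, max_iter = 100,
                           tol = 1e-6, nodes = NULL) {
  if (is.matrix(graph)) {
    A <- graph
    if (is.null(rownames(A))) stop_("adjacency matrix must be named")
    nodes <- sort(unique(c(rownames(A), nodes)))
    A <- A[nodes, nodes]
  } else {
    if (nrow(graph) && any(graph$weight <= 0)) stop_("edge weights must be > 0")
    nodes <- sort(unique(c(graph$from, graph$to, nodes)))
    A <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    for (k in seq_len(nrow(graph))) {
      i <- graph$from[k]; j <- graph$to[k]
      A[i, j] <- max(A[i, j], graph$weight[k])
      A[j, i] <- A[i, j]
    }
  }
  n <- length(nodes)
  if (n == 0L) return(structure(list(groups = list(), converged = TRUE,
                                     n_iter = 0L), class = "mcl_partition"))
  loop <- apply(A, 1L, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2L, colSums(A), "/")
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < tol] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2L, cs, "/")
    if (max(abs(M2 - M)) < tol) { M <- M2; converged <- TRUE; break }
    M <- M2
  }
  if (!converged)
    warning("MCL did not converge within ", max_iter, " iterations",
            call. = FALSE)
  support <- (M > tol) | (t(M) > tol)
  diag(support) <- TRUE
  comp <- components_of(support)
  groups <- lapply(split(nodes, comp), sort)
  groups <- groups[order(vapply(groups, `[`, "", 1L))]
  names(groups) <- paste0("G", seq_along(groups))
  structure(list(groups = groups, converged = converged, n_iter = it),
            class = "mcl_partition")
}

# connected components of a logical adjacency matrix (simple BFS)
components_of <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' @export
print.mcl_partition <- function(x, ...) {
  cat(sprintf("MCL partition: %d group(s)%s, %d iteration(s)\n",
              length(x$groups),
              if (x$converged) "" else " (NOT converged)", x$n_iter))
  invisible(x)
}

#' Ortholog groups as a table
#'
#' @param partition An `"mcl_partition"`.
#' @param species Optional function or named vector mapping accession to
#'   species label.
#' @param confirmed Optional named logical vector per group id.
#' @return Data frame `group_id`, `species`, `accession`, `confirmed`.
#' @export
ortholog_groups <- function(partition, species = NULL, confirmed = NULL) {
  rows <- lapply(names(partition$groups), function(g) {
    acc <- partition$groups[[g]]
    sp <- if (is.function(species)) vapply(acc, species, "")
          else if (!is.null(species)) unname(species[acc])
          else NA_character_
    data.frame(group_id = g, species = sp, accession = acc,
               confirmed = if (!is.null(confirmed)) confirmed[[g]] else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# multiset Jaccard similarity of two token vectors
multiset_jaccard <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  ta <- table(a); tb <- table(b)
  toks <- union(names(ta), names(tb))
  ca <- as.numeric(ta[toks]); ca[is.na(ca)] <- 0
  cb <- as.numeric(tb[toks]); cb[is.na(cb)] <- 0
  sum(pmin(ca, cb)) / sum(pmax(ca, cb))
}

#' Confirm an ortholog group by domain architecture
#'
#' Operationalises "similar domain structure": the group is confirmed when
#' every pair of members (with known architecture) has a multiset Jaccard
#' similarity of their domain tokens >= 0.5. With architectures for fewer
#' than two members the answer is unknown (`NA`, distinct from `FALSE`).
#'
#' @param members Character vector of member accessions.
#' @param architectures Named list: accession -> character vector of
#'   ordered domain-identifier tokens.
#' @return `TRUE`, `FALSE` or `NA`.
#' @examples
#' confirm_group_domains(c("a", "b"),
#'   list(a = c("HATPase_c", "REC"), b = c("HATPase_c", "REC")))
#' @export
confirm_group_domains <- function(members, architectures) {
  known <- members[members %in% names(architectures)]
  if (length(known) < 2L) return(NA)
  pairs <- utils::combn(known, 2L)
  for (k in seq_len(ncol(pairs))) {
    j <- multiset_jaccard(architectures[[pairs[1L, k]]],
                          architectures[[pairs[2L, k]]])
    if (j < 0.5) return(FALSE)
  }
  TRUE
}

#' Read a domain-architecture table
#'
#' TSV with columns `accession` and `domains` (comma- or space-separated
#' ordered tokens).
#'
#' @param path Path to the TSV file.
#' @return Named list: accession -> character vector of tokens.
#' @export
read_domain_architectures <- function(path) {
  df <- read_tsv(path)
  if (!all(c("accession", "domains") %in% names(df)))
    stop_("domain table needs columns: accession, domains")
  stats::setNames(lapply(df$domains,
                         function(d) strsplit(trimws(d), "[,[:space:]]+")[[1L]]),
                  df$accession)
}
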