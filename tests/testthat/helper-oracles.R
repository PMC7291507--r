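# Independent oracles, deliberately naive, used to cross-check the
# implementation. They never call the code paths they verify.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# Gotoh local alignment by full dynamic programming; a gap of length g
# costs open + g * ext; the empty alignment scores 0.
sw_oracle <- function(a, b, mat = blosum62, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)
  F <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in 2:(n + 1L)) for (j in 2:(m + 1L)) {
    E[i, j] <- max(H[i, j - 1L] - open - ext, E[i, j - 1L] - ext)
    F[i, j] <- max(H[i - 1L, j] - open - ext, F[i - 1L, j] - ext)
    H[i, j] <- max(0, H[i - 1L, j - 1L] + mat[A[i - 1L], B[j - 1L]],
                   E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# closed-form pooled two-sample t on log2 values
t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tt, p = 2 * pt(-abs(tt), nx + ny - 2))
}

# dense expansion/inflation reference loop (no pruning while iterating)
mcl_oracle <- function(edges, nodes, inflation = 1.5, tol = 1e-6,
                       max_iter = 100) {
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) {
    A[edges$from[k], edges$to[k]] <-
      max(A[edges$from[k], edges$to[k]], edges$weight[k])
    A[edges$to[k], edges$from[k]] <- A[edges$from[k], edges$to[k]]
  }
  loop <- apply(A, 1L, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2L, colSums(A), "/")
  for (it in seq_len(max_iter)) {
    Mn <- (M %*% M)^inflation
    Mn <- sweep(Mn, 2L, colSums(Mn), "/")
    if (max(abs(Mn - M)) < tol) { M <- Mn; break }
    M <- Mn
  }
  sup <- (M > tol) | t(M > tol)
  diag(sup) <- TRUE
  comp <- rep(NA_integer_, length(nodes))
  cur <- 0L
  for (s in seq_along(nodes)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    q <- s; comp[s] <- cur
    while (length(q)) {
      v <- q[1L]; q <- q[-1L]
      nb <- which(sup[v, ] & is.na(comp))
      comp[nb] <- cur
      q <- c(q, nb)
    }
  }
  unname(lapply(split(nodes, comp), sort))
}

# brute-force breadth-first neighbourhood on an undirected edge list
bfs_oracle <- function(edges, seed, radius) {
  frontier <- seed
  seen <- seed
  for (r in seq_len(radius)) {
    nb <- c(edges$target[edges$source %in% frontier],
            edges$source[edges$target %in% frontier])
    frontier <- setdiff(nb, seen)
    if (!length(frontier)) break
    seen <- c(seen, frontier)
  }
  sort(unique(seen))
}

# naive O(n^3) average-linkage clustering, reported as the cophenetic
# distance matrix (merge heights between every leaf pair)
avg_linkage_cophenetic_oracle <- function(X) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  coph <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  cl <- lapply(seq_len(n), identity)
  while (length(cl) > 1L) {
    bd <- Inf; best <- c(NA, NA)
    for (i in seq_along(cl)) for (j in seq_len(i - 1L)) {
      d <- mean(D[cl[[i]], cl[[j]], drop = FALSE])
      if (d < bd) { bd <- d; best <- c(j, i) }
    }
    a <- cl[[best[1L]]]; b <- cl[[best[2L]]]
    coph[a, b] <- bd; coph[b, a] <- bd
    cl[[best[1L]]] <- c(a, b)
    cl[[best[2L]]] <- NULL
  }
  coph
}

partition_key <- function(groups) {
  sort(unname(vapply(groups, function(g) paste(sort(g), collapse = ","), "")))
}

random_aa <- function(len, chars = rownames(blosum62)[1:20]) {
  paste(sample(chars, len, replace = TRUE), collapse = "")
}
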