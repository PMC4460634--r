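# Independent straight-line reference implementations used as oracles.
# These deliberately share nothing with the package internals beyond the
# exported bootstrap index streams and (where stated) a shared null pool.

# Pairwise mutual information by direct per-pair evaluation.
oracle_mi <- function(m) {
  p <- nrow(m)
  I <- matrix(0, p, p, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      r <- cor(m[i, ], m[j, ])
      r2 <- min(r^2, 1 - 1e-12)
      I[i, j] <- -0.5 * log(1 - r2)
    }
  }
  I
}

# Brute-force C3Net: full MI matrix, per-gene argmax (lexicographic smallest
# partner on ties), empirical p with +1 correction, Bonferroni by gene count.
# Returns a sorted character vector of "a|b" edge keys (a < b).
oracle_c3net_edges <- function(m, pool_values, alpha = 0.05) {
  sds <- apply(m, 1, sd)
  m <- m[sds > 0, , drop = FALSE]
  ids <- rownames(m)
  p <- nrow(m)
  if (p < 2) return(character())
  I <- oracle_mi(m)
  kept <- character()
  for (i in seq_len(p)) {
    best_mi <- -Inf
    best_j <- NA_integer_
    for (j in seq_len(p)) {
      if (j == i) next
      better <- I[i, j] > best_mi ||
        (I[i, j] == best_mi && ids[j] < ids[best_j])
      if (better) {
        best_mi <- I[i, j]
        best_j <- j
      }
    }
    p_emp <- (1 + sum(pool_values >= best_mi)) / (length(pool_values) + 1)
    if (min(1, p_emp * p) <= alpha) {
      a <- min(ids[i], ids[best_j])
      b <- max(ids[i], ids[best_j])
      kept <- c(kept, paste(a, b, sep = "|"))
    }
  }
  sort(unique(kept))
}

# Brute-force BC3Net over the exported bootstrap index streams, with the
# same shared null pool.
oracle_bc3net_edges <- function(m, B, seed, pool_values, alpha_edge = 0.05,
                                alpha_c3 = 0.05) {
  n <- ncol(m)
  p <- nrow(m)
  counts <- list()
  for (b in seq_len(B)) {
    idx <- grngpea::bootstrap_indices(n, seed, b)
    mb <- m[, idx, drop = FALSE]
    colnames(mb) <- sprintf("bs%03d", seq_len(n))
    for (key in oracle_c3net_edges(mb, pool_values, alpha = alpha_c3)) {
      counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
    }
  }
  if (!length(counts)) return(list(edges = character(), ecr = numeric()))
  keys <- sort(names(counts))
  k_e <- unlist(counts[keys])
  N <- p * (p - 1) / 2
  theta0 <- sum(k_e) / (B * N)
  pvals <- numeric(length(keys))
  for (i in seq_along(keys)) {
    pvals[i] <- sum(dbinom(k_e[i]:B, B, theta0))
  }
  p_adj <- pmin(1, pvals * length(keys))
  keep <- p_adj <= alpha_edge
  list(edges = keys[keep], ecr = unname(k_e[keep] / B))
}

# Exhaustive-enumeration hypergeometric upper tail: draw n of the N pair
# slots (the first m_S are "in set"), count draws with >= k in-set slots.
oracle_gpea_enumeration <- function(k, m_S, n, N) {
  if (k <= 0) return(1)
  draws <- combn(N, n)
  hits <- colSums(draws <= m_S)
  mean(hits >= k)
}

edge_key_set <- function(net) {
  paste(net$edges$gene_a, net$edges$gene_b, sep = "|")
}
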