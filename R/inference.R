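#' Mutual information between two vectors via the Pearson estimator
#'
#' Under a bivariate Gaussian model the mutual information is a closed form
#' of the Pearson correlation rho:
#' \deqn{I(X,Y) = -\tfrac{1}{2}\log(1-\rho^2).}
#' To keep duplicated profiles (|rho| = 1) finite, rho^2 is capped at
#' 1 - 1e-12.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return Non-negative mutual information (nats).
#' @export
mi_pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  mi_from_rho(cor(x, y))
}

MI_RHO2_CAP <- 1 - 1e-12

mi_from_rho <- function(rho) {
  rho2 <- pmin(rho^2, MI_RHO2_CAP)
  -0.5 * log1p(-rho2)
}

#' All-pairs mutual information matrix
#'
#' Computes the Pearson correlation matrix across genes and maps it through
#' the Gaussian mutual-information form (see [mi_pearson()]). The diagonal is
#' set to zero by convention.
#'
#' @param m Expression matrix (genes x samples), zero-SD genes removed,
#'   >= 3 samples.
#' @return List with `gene_ids`, symmetric non-negative matrix `values`, and
#'   the underlying correlation matrix `rho`.
#' @export
mi_matrix <- function(m) {
  check_expression(m)
  if (ncol(m) < 3L) stop("need at least 3 samples")
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    stop("constant gene(s) present: ",
         paste(head(rownames(m)[sds == 0]), collapse = ", "))
  }
  rho <- cor(t(m))
  values <- mi_from_rho(rho)
  diag(values) <- 0
  list(gene_ids = rownames(m), values = values, rho = rho)
}

#' Null distribution of mutual information by sample-label permutation
#'
#' Each draw picks a random gene pair, independently permutes each gene's
#' sample order (destroying any dependence while preserving the marginals),
#' and records the resulting mutual information. The pool is shared across
#' all edge tests of a dataset.
#'
#' @param m Expression matrix (genes x samples).
#' @param n_draws Number of null draws (default 100000; a warning is issued
#'   below 1000 because the tail becomes unstable).
#' @param seed Integer seed; the pool is a pure function of `(m, n_draws, seed)`.
#' @return List of class `null_mi_pool` with `values`, `n_draws`, `seed`.
#' @export
null_mi_pool <- function(m, n_draws = 100000L, seed = 1L) {
  check_expression(m)
  if (nrow(m) < 2L) stop("need at least 2 genes")
  n_draws <- as.integer(n_draws)
  if (n_draws < 1000L) warning("fewer than 1000 null draws: unstable tail")
  n <- ncol(m)
  values <- with_seed(seed, {
    out <- numeric(n_draws)
    chunk <- 2000L
    done <- 0L
    while (done < n_draws) {
      k <- min(chunk, n_draws - done)
      gi <- sample.int(nrow(m), k, replace = TRUE)
      gj <- sample.int(nrow(m), k, replace = TRUE)
      clash <- gi == gj
      while (any(clash)) {
        gj[clash] <- sample.int(nrow(m), sum(clash), replace = TRUE)
        clash <- gi == gj
      }
      x <- matrix(0, nrow = n, ncol = k)
      y <- matrix(0, nrow = n, ncol = k)
      for (c in seq_len(k)) {
        x[, c] <- m[gi[c], sample.int(n)]
        y[, c] <- m[gj[c], sample.int(n)]
      }
      x <- scale(x)
      y <- scale(y)
      rho <- colSums(x * y) / (n - 1)
      out[done + seq_len(k)] <- mi_from_rho(rho)
      done <- done + k
    }
    out
  })
  structure(list(values = values, n_draws = n_draws, seed = as.integer(seed)),
            class = "null_mi_pool")
}

# Empirical upper-tail p-value with the +1 correction. Counts pool values
# >= stat via a sorted lookup: findInterval with left.open gives #{pool < s}.
empirical_pvalue <- function(stat, pool_values) {
  sorted <- sort(pool_values)
  n_below <- findInterval(stat, sorted, left.open = TRUE)
  (1 + (length(sorted) - n_below)) / (length(sorted) + 1)
}

#' C3Net: one strongest significant partner per gene
#'
#' For each gene, its single maximal-mutual-information partner is a
#' candidate edge (argmax ties broken by the lexicographically smallest
#' partner identifier). A candidate is kept iff its empirical permutation
#' p-value, Bonferroni-multiplied by the number of candidate genes, is at
#' most `alpha`. The union of kept candidates (deduplicated) is the network,
#' so the edge count never exceeds the gene count.
#'
#' @param m Expression matrix (genes x samples).
#' @param alpha Significance level for the Bonferroni-adjusted permutation
#'   test (default 0.05).
#' @param pool Null MI pool from [null_mi_pool()]; computed on the fly (seed
#'   1, 100000 draws) when missing.
#' @param on_constant `"error"` (default) to refuse constant genes, `"drop"`
#'   to exclude them from candidacy (used internally on bootstrap replicates,
#'   where resampling can flatten a gene).
#' @return A `grn_network` with `ecr = 1` and the adjusted permutation
#'   p-value per edge (the smaller one when both endpoints proposed the edge).
#' @export
c3net <- function(m, alpha = 0.05, pool = NULL,
                  on_constant = c("error", "drop")) {
  on_constant <- match.arg(on_constant)
  check_expression(m)
  sds <- apply(m, 1, sd)
  active <- sds > 0
  if (!all(active) && on_constant == "error") {
    stop("constant gene(s) present: ",
         paste(head(rownames(m)[!active]), collapse = ", "))
  }
  if (sum(active) < 2L) {
    return(grn_network(rownames(m), NULL, B = 1L))
  }
  if (is.null(pool)) pool <- null_mi_pool(m[active, , drop = FALSE])
  mm <- mi_matrix(m[active, , drop = FALSE])
  ids <- mm$gene_ids
  vals <- mm$values
  p <- length(ids)
  # per-gene argmax with lexicographic tie-break: column order of `vals`
  # follows row order of m; rank partners by (-MI, id)
  partner <- integer(p)
  id_rank <- rank(ids, ties.method = "first")
  for (i in seq_len(p)) {
    row <- vals[i, ]
    row[i] <- -Inf
    best <- which(row == max(row))
    partner[i] <- best[which.min(id_rank[best])]
  }
  cand_mi <- vals[cbind(seq_len(p), partner)]
  p_emp <- empirical_pvalue(cand_mi, pool$values)
  p_adj <- pmin(1, p_emp * p)
  keep <- p_adj <= alpha
  if (!any(keep)) {
    warning("no significant candidate edges; returning empty network")
    return(grn_network(rownames(m), NULL, B = 1L))
  }
  edges <- data.frame(gene_a = ids[keep], gene_b = ids[partner[keep]],
                      ecr = 1, pvalue_adj = p_adj[keep],
                      stringsAsFactors = FALSE)
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  key <- paste(edges$gene_a, edges$gene_b, sep = "\r")
  ord <- order(key, edges$pvalue_adj)
  edges <- edges[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  grn_network(rownames(m), edges, B = 1L)
}

#' Bootstrap sample-index stream for one ensemble member
#'
#' The index stream is a pure function of `(seed, b)` so ensemble results are
#' reproducible regardless of evaluation order. Exposed so that reference
#' implementations can consume identical streams.
#'
#' @param n Number of samples.
#' @param seed Ensemble seed.
#' @param b Bootstrap iteration (1-based).
#' @return Integer vector of length `n`, sampled with replacement.
#' @export
bootstrap_indices <- function(n, seed, b) {
  with_seed(child_seed(seed, 1000L + b), sample.int(n, n, replace = TRUE))
}

#' BC3Net: bootstrap-aggregated C3Net with binomial edge significance
#'
#' Runs C3Net on `B` bootstrap datasets (samples resampled with replacement,
#' size preserved), aggregates edge occurrence counts `k_e` over the
#' ensemble, and assigns each aggregated edge the ensemble consensus rate
#' `ecr = k_e / B`. Each edge is then tested one-sided against
#' `Binomial(B, theta0)` where `theta0` is the expected per-pair occurrence
#' rate `sum(k_e) / (B * N)` with `N = p(p-1)/2` possible pairs; p-values are
#' Bonferroni-corrected by the number of distinct aggregated edges, and edges
#' with adjusted p <= `alpha_edge` are retained. One permutation null pool
#' (computed from the original matrix) is shared across the ensemble.
#'
#' @param m Expression matrix (genes x samples).
#' @param B Ensemble size (default 100).
#' @param alpha_edge Significance level of the binomial consensus test.
#' @param alpha_c3 Significance level passed to each C3Net run.
#' @param seed Integer seed controlling the bootstrap index streams.
#' @param n_draws Size of the shared permutation null pool.
#' @param resample Set `FALSE` to disable resampling (every ensemble member
#'   sees the original data); with `B = 1` this reduces BC3Net to C3Net.
#' @param pool Optional pre-computed [null_mi_pool()] shared across the
#'   ensemble; computed from `m` (seed derived from `seed`) when missing.
#' @return A `grn_network` with per-edge `ecr` and adjusted binomial p-value.
#' @export
bc3net <- function(m, B = 100L, alpha_edge = 0.05, alpha_c3 = 0.05,
                   seed = 1L, n_draws = 100000L, resample = TRUE,
                   pool = NULL) {
  check_expression(m)
  B <- as.integer(B)
  if (B < 1L) stop("B must be >= 1")
  n <- ncol(m)
  p <- nrow(m)
  if (is.null(pool)) {
    pool <- null_mi_pool(m, n_draws = n_draws, seed = child_seed(seed, 0L))
  }
  counts <- new.env(parent = emptyenv())
  for (b in seq_len(B)) {
    idx <- if (resample) bootstrap_indices(n, seed, b) else seq_len(n)
    mb <- m[, idx, drop = FALSE]
    colnames(mb) <- make.unique(colnames(m)[idx])
    gb <- suppressWarnings(
      c3net(mb, alpha = alpha_c3, pool = pool, on_constant = "drop")
    )
    if (nrow(gb$edges)) {
      for (key in edge_keys(gb)) {
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  keys <- sort(ls(counts))
  if (!length(keys)) {
    warning("empty aggregated ensemble network")
    return(grn_network(rownames(m), NULL, B = B))
  }
  k_e <- vapply(keys, function(k) counts[[k]], integer(1))
  N <- p * (p - 1) / 2
  theta0 <- sum(k_e) / (B * N)
  p_binom <- pbinom(k_e - 1L, size = B, prob = theta0, lower.tail = FALSE)
  p_adj <- pmin(1, p_binom * length(keys))
  keep <- p_adj <= alpha_edge
  ab <- strsplit(keys[keep], "\r", fixed = TRUE)
  edges <- data.frame(
    gene_a = vapply(ab, `[[`, character(1), 1L),
    gene_b = vapply(ab, `[[`, character(1), 2L),
    ecr = k_e[keep] / B,
    pvalue_adj = p_adj[keep],
    stringsAsFactors = FALSE
  )
  grn_network(rownames(m), edges, B = B)
}

#' Relevance networks by hard thresholding
#'
#' Two baselines against which the ensemble GRN is compared:
#' `abscorr` thresholds the absolute Pearson correlation matrix;
#' `clr` computes per-gene z-scores of the mutual-information matrix,
#' `z_i(j) = (I_ij - mean_i) / sd_i`, combines them symmetrically as
#' `sqrt(max(0, z_i)^2 + max(0, z_j)^2)`, and thresholds that score.
#' The threshold is the given percentile of all off-diagonal scores; pairs
#' strictly above it become edges (for distinct scores this keeps exactly
#' `ceil((1 - percentile) * N)` pairs; ties at the threshold keep all tied
#' pairs).
#'
#' @param m Expression matrix (genes x samples).
#' @param method `"abscorr"` or `"clr"`.
#' @param percentile Hard threshold percentile in (0, 1).
#' @return A `grn_network` with the pair score as `ecr` weight.
#' @export
relevance_network <- function(m, method = c("abscorr", "clr"), percentile = 0.9) {
  method <- match.arg(method)
  if (percentile <= 0 || percentile >= 1) stop("percentile must be in (0,1)")
  mm <- mi_matrix(m)
  ids <- mm$gene_ids
  score <- if (method == "abscorr") {
    abs(mm$rho)
  } else {
    I <- mm$values
    p <- nrow(I)
    mu <- rowSums(I) / (p - 1)      # diagonal is zero by convention
    sdv <- vapply(seq_len(p), function(i) sd(I[i, -i]), numeric(1))
    if (any(sdv == 0)) stop("degenerate MI matrix: constant row scores")
    z <- (I - mu) / sdv           # z_i(j) in row i
    z[z < 0] <- 0
    sqrt(z^2 + t(z)^2)
  }
  ut <- upper.tri(score)
  vals <- score[ut]
  if (max(vals) == min(vals)) stop("degenerate score matrix: all pair scores equal")
  thr <- quantile(vals, percentile, names = FALSE)
  sel <- which(score > thr & ut, arr.ind = TRUE)
  if (!nrow(sel)) return(grn_network(ids, NULL, B = 1L))
  edges <- data.frame(gene_a = ids[sel[, 1]], gene_b = ids[sel[, 2]],
                      ecr = score[sel], pvalue_adj = NA_real_,
                      stringsAsFactors = FALSE)
  grn_network(ids, edges, B = 1L)
}
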