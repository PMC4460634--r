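#' Hypergeometric gene-pair enrichment p-value
#'
#' Probability of observing `k` or more network edges among the gene pairs
#' of a gene set. With `N = p(p-1)/2` possible pairs over the `p`-gene
#' universe, `m_S = p_S(p_S-1)/2` pairs inside a set of `p_S` genes, and `n`
#' edges in the network, the upper tail is
#' \deqn{p(k|S) = \sum_{i=k}^{m_S} \binom{m_S}{i}\binom{N-m_S}{n-i} / \binom{N}{n}.}
#' The sum is evaluated in log space (log-binomials combined by
#' log-sum-exp), which keeps tiny tail probabilities accurate for the
#' network-scale counts this is used with.
#'
#' @param k Observed within-set edge count.
#' @param m_S Number of gene pairs inside the set.
#' @param n Number of network edges.
#' @param N Total number of gene pairs in the universe.
#' @return Upper-tail probability in (0, 1]; exactly 1 when `k <= 0`.
#' @export
gpea_pvalue <- function(k, m_S, n, N) {
  if (any(c(k, m_S, n, N) < 0) || m_S > N || n > N) {
    stop("inconsistent counts: need 0 <= m_S <= N and 0 <= n <= N")
  }
  if (k > m_S || k > n) {
    stop("k cannot exceed m_S or n")
  }
  if (k <= 0) return(1)
  i_max <- min(m_S, n)
  i_min <- max(k, n - (N - m_S))   # lower support bound of the hypergeometric
  if (i_min > i_max) return(0)
  i <- i_min:i_max
  log_terms <- lchoose(m_S, i) + lchoose(N - m_S, n - i) - lchoose(N, n)
  mx <- max(log_terms)
  min(1, exp(mx + log(sum(exp(log_terms - mx)))))
}

#' Gene-pair enrichment analysis over a gene-set collection
#'
#' For each gene set (intersected with the network's node universe): counts
#' the network edges with both endpoints in the set and computes the
#' hypergeometric upper-tail p-value of [gpea_pvalue()]. The universe is the
#' network node set because only network genes can form edges. P-values are
#' corrected over the number of tested sets (Bonferroni by default;
#' Benjamini-Hochberg FDR optionally, as used for subnetwork comparisons).
#' Sets with no member in the network are excluded from testing.
#'
#' @param net A `grn_network`.
#' @param sets A `gene_set_collection` (ideally pre-filtered with
#'   [filter_collection()] against the network nodes).
#' @param alpha Significance level on the adjusted p-value (default 0.001,
#'   the stringent level appropriate when the number of tests is around
#'   10^3).
#' @param correction `"bonferroni"` or `"fdr"` (Benjamini-Hochberg).
#' @return Data frame of class `gpea_result`, sorted by adjusted then raw
#'   p-value, with columns `set_name`, `p_genes`, `N`, `p_S`, `m_S`,
#'   `n_edges`, `k`, `p_raw`, `p_adj`, `significant`, and a list column
#'   `subnetwork` holding each set's within-set edge table.
#' @export
run_gpea <- function(net, sets, alpha = 0.001,
                     correction = c("bonferroni", "fdr")) {
  correction <- match.arg(correction)
  stopifnot(inherits(net, "grn_network"), inherits(sets, "gene_set_collection"))
  universe <- net$nodes
  p_genes <- length(universe)
  N <- p_genes * (p_genes - 1) / 2
  n_edges <- nrow(net$edges)
  members_list <- lapply(sets$sets, function(s) intersect(s, universe))
  tested <- names(members_list)[lengths(members_list) > 0]
  if (!length(tested)) stop("no gene set overlaps the network universe")
  in_set <- function(members) {
    sel <- net$edges$gene_a %in% members & net$edges$gene_b %in% members
    net$edges[sel, , drop = FALSE]
  }
  sub <- lapply(members_list[tested], in_set)
  p_S <- lengths(members_list[tested])
  m_S <- p_S * (p_S - 1) / 2
  k <- vapply(sub, nrow, integer(1))
  p_raw <- mapply(gpea_pvalue, k, m_S, MoreArgs = list(n = n_edges, N = N))
  p_adj <- if (correction == "bonferroni") {
    pmin(1, p_raw * length(tested))
  } else {
    stats::p.adjust(p_raw, method = "BH")
  }
  out <- data.frame(set_name = tested, p_genes = p_genes, N = N,
                    p_S = as.integer(p_S), m_S = m_S, n_edges = n_edges,
                    k = as.integer(k), p_raw = p_raw, p_adj = p_adj,
                    significant = p_adj <= alpha,
                    stringsAsFactors = FALSE)
  out$subnetwork <- unname(sub)
  ord <- order(out$p_adj, out$p_raw, out$set_name, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "correction") <- correction
  attr(out, "n_excluded") <- length(members_list) - length(tested)
  class(out) <- c("gpea_result", "data.frame")
  out
}

#' Census-gene enrichment of significant subnetworks
#'
#' Secondary, gene-based enrichment: for each GPEA result, the genes
#' incident to at least one within-set edge are tested for
#' over-representation of a curated census gene list (one-sided
#' hypergeometric over genes, universe = network nodes).
#'
#' @param results A `gpea_result` (typically subset to significant rows).
#' @param census Character vector of census gene identifiers.
#' @param universe Network node universe the enrichment is computed over.
#' @return Data frame with `set_name`, `n_subnet_genes`, `n_census_in_subnet`,
#'   `census_genes` (comma-separated), and `p_census`.
#' @export
census_enrichment <- function(results, census, universe) {
  stopifnot(inherits(results, "gpea_result"))
  census <- unique(as.character(census))
  if (!length(census)) stop("empty census gene list")
  census_u <- intersect(census, universe)
  U <- length(universe)
  K <- length(census_u)
  rows <- lapply(seq_len(nrow(results)), function(i) {
    sub <- results$subnetwork[[i]]
    genes <- unique(c(sub$gene_a, sub$gene_b))
    s <- length(genes)
    hits <- intersect(genes, census_u)
    x <- length(hits)
    p <- if (s == 0) 1 else phyper(x - 1, K, U - K, s, lower.tail = FALSE)
    data.frame(set_name = results$set_name[i], n_subnet_genes = s,
               n_census_in_subnet = x,
               census_genes = paste(sort(hits), collapse = ","),
               p_census = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a GPEA result table to TSV
#'
#' Serializes the scalar columns (the `subnetwork` list column is written as
#' semicolon-separated `a-b` pairs).
#'
#' @param results A `gpea_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gpea <- function(results, path) {
  stopifnot(inherits(results, "gpea_result"))
  flat <- as.data.frame(results[, setdiff(names(results), "subnetwork")])
  flat$edges <- vapply(results$subnetwork, function(e) {
    paste(paste(e$gene_a, e$gene_b, sep = "-"), collapse = ";")
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# grngpea %s gpea alpha=%g correction=%s sets_tested=%d",
                     as.character(packageVersion("grngpea")),
                     attr(results, "alpha"), attr(results, "correction"),
                     nrow(results)), con)
  write.table(flat, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
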