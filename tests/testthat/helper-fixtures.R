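# Small in-code fixtures shared across test files.

# Random expression matrix of independent genes.
random_expression <- function(p = 10, n = 50, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(p * n), nrow = p,
              dimnames = list(sprintf("g%02d", seq_len(p)),
                              sprintf("s%02d", seq_len(n))))
  m
}

# Expression matrix where listed gene pairs are strongly coupled
# (shared latent factor), the rest independent noise.
coupled_expression <- function(p = 8, n = 60, pairs = list(c(1, 2)),
                               coupling = 0.9, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(p * n), nrow = p)
  for (pr in pairs) {
    z <- rnorm(n)
    m[pr[1], ] <- coupling * z + sqrt(1 - coupling^2) * rnorm(n)
    m[pr[2], ] <- coupling * z + sqrt(1 - coupling^2) * rnorm(n)
  }
  dimnames(m) <- list(sprintf("g%02d", seq_len(p)), sprintf("s%02d", seq_len(n)))
  m
}

# A small deterministic network over named genes.
toy_network <- function(edges, nodes = NULL) {
  df <- data.frame(gene_a = vapply(edges, `[[`, character(1), 1),
                   gene_b = vapply(edges, `[[`, character(1), 2),
                   stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- sort(unique(c(df$gene_a, df$gene_b)))
  grn_network(nodes, df)
}

# Erdos-Renyi style G(n, m) network with deterministic labels.
random_network <- function(p = 50, n_edges = 100, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("g%03d", seq_len(p))
  all_pairs <- t(combn(p, 2))
  sel <- sample.int(nrow(all_pairs), n_edges)
  grn_network(nodes, data.frame(gene_a = nodes[all_pairs[sel, 1]],
                                gene_b = nodes[all_pairs[sel, 2]],
                                stringsAsFactors = FALSE))
}

write_expression_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
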