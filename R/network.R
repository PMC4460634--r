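#' Construct a weighted undirected network
#'
#' The package's network container: a simple undirected graph over gene
#' identifiers with one row per edge carrying the ensemble consensus rate
#' (ECR; the fraction of bootstrap networks in which the edge occurred) and a
#' multiple-testing-adjusted p-value. Edges are stored canonically with
#' `gene_a < gene_b` lexicographically; all set operations in the package rely
#' on that canonical form.
#'
#' @param nodes Character vector of node (gene) identifiers.
#' @param edges Data frame with columns `gene_a`, `gene_b` and optionally
#'   `ecr` (default 1) and `pvalue_adj` (default `NA`).
#' @param B Ensemble size that produced the ECR values (1 for single-run
#'   networks such as C3Net or relevance networks).
#' @return An object of class `grn_network`: a list with elements `nodes`,
#'   `edges` (canonical edge data frame) and `B`.
#' @export
grn_network <- function(nodes, edges = NULL, B = 1L) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node identifiers")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        ecr = numeric(), pvalue_adj = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("gene_a", "gene_b") %in% names(edges))) {
      stop("edges must have columns gene_a and gene_b")
    }
    if (is.null(edges$ecr)) edges$ecr <- 1
    if (is.null(edges$pvalue_adj)) edges$pvalue_adj <- NA_real_
    edges <- canonicalize_edges(edges, merge = "error")
    missing_nodes <- setdiff(unique(c(edges$gene_a, edges$gene_b)), nodes)
    if (length(missing_nodes)) {
      stop("edge endpoints not in node set: ", paste(head(missing_nodes), collapse = ", "))
    }
  }
  structure(list(nodes = nodes, edges = edges, B = as.integer(B)),
            class = "grn_network")
}

#' @export
print.grn_network <- function(x, ...) {
  cat(sprintf("grn_network: %d nodes, %d edges (B = %d)\n",
              length(x$nodes), nrow(x$edges), x$B))
  invisible(x)
}

# Canonicalize an edge table: order endpoints lexicographically, drop
# self-loops (counted), and merge duplicate unordered pairs.
# merge = "max" keeps the maximum weight (reader policy), "error" refuses
# duplicates (constructor policy).
canonicalize_edges <- function(edges, merge = c("max", "error")) {
  merge <- match.arg(merge)
  edges$gene_a <- as.character(edges$gene_a)
  edges$gene_b <- as.character(edges$gene_b)
  loops <- edges$gene_a == edges$gene_b
  n_loops <- sum(loops)
  if (n_loops > 0L) {
    warning(sprintf("dropped %d self-loop edge(s)", n_loops))
    edges <- edges[!loops, , drop = FALSE]
  }
  swap <- edges$gene_a > edges$gene_b
  if (any(swap)) {
    tmp <- edges$gene_a[swap]
    edges$gene_a[swap] <- edges$gene_b[swap]
    edges$gene_b[swap] <- tmp
  }
  key <- paste(edges$gene_a, edges$gene_b, sep = "\r")
  if (anyDuplicated(key)) {
    if (merge == "error") stop("duplicate edges after canonicalization")
    ord <- order(key, -edges$ecr)
    edges <- edges[ord, , drop = FALSE]
    edges <- edges[!duplicated(key[ord]), , drop = FALSE]
  }
  edges <- edges[order(edges$gene_a, edges$gene_b, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "n_loops_dropped") <- n_loops
  edges
}

# "a\rb" keys for canonical edges; used for all edge-set arithmetic.
edge_keys <- function(net) {
  e <- if (inherits(net, "grn_network")) net$edges else net
  paste(e$gene_a, e$gene_b, sep = "\r")
}

#' Convert a network to an igraph object
#'
#' @param net A `grn_network`.
#' @return An undirected simple `igraph` graph with all nodes (including
#'   isolated ones) and an `ecr` edge attribute.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "grn_network"))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("gene_a", "gene_b"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = net$nodes)
  )
  if (nrow(net$edges)) igraph::E(g)$ecr <- net$edges$ecr
  g
}

#' Read a network edge list from a TSV file
#'
#' Accepts 2--4 columns (`gene_a`, `gene_b`, optional `weight`, optional
#' adjusted p-value). Lines starting with `#` are ignored. The result is a
#' canonical undirected simple graph: reversed duplicate pairs are merged
#' keeping the maximum weight; self-loop rows are dropped with a warning.
#'
#' @param path File path.
#' @param nodes Optional full node universe; defaults to the genes incident
#'   to at least one edge.
#' @return A `grn_network`.
#' @export
read_network <- function(path, nodes = NULL) {
  raw <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop("network file must have at least two columns: ", path)
  edges <- data.frame(gene_a = raw[[1]], gene_b = raw[[2]],
                      stringsAsFactors = FALSE)
  edges$ecr <- if (ncol(raw) >= 3L) as.numeric(raw[[3]]) else 1
  edges$pvalue_adj <- if (ncol(raw) >= 4L) as.numeric(raw[[4]]) else NA_real_
  edges <- canonicalize_edges(edges, merge = "max")
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  grn_network(nodes, edges, B = 1L)
}

#' Write a network edge list to a TSV file
#'
#' Emits a header comment line with the package version and the ensemble size,
#' then one row per canonical edge: `gene_a`, `gene_b`, `ecr`, `pvalue_adj`.
#'
#' @param net A `grn_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "grn_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# grngpea %s network B=%d nodes=%d edges=%d",
                     as.character(packageVersion("grngpea")),
                     net$B, length(net$nodes), nrow(net$edges)), con)
  write.table(net$edges, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
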