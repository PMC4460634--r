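#' Degree centrality table
#'
#' Number of direct neighbors per gene, for every node of the network
#' (isolated nodes get degree 0).
#'
#' @param net A `grn_network`.
#' @return Named integer vector over `net$nodes`.
#' @export
degree_centrality <- function(net) {
  stopifnot(inherits(net, "grn_network"))
  d <- setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    tab <- table(c(net$edges$gene_a, net$edges$gene_b))
    d[names(tab)] <- as.integer(tab)
  }
  d
}

#' Top hub genes by degree
#'
#' @param net A `grn_network`.
#' @param top Number of hubs to report.
#' @return Data frame (`gene_id`, `degree`) ordered by degree descending,
#'   ties by identifier ascending.
#' @export
hub_table <- function(net, top = 25L) {
  d <- degree_centrality(net)
  ord <- order(-d, names(d), method = "radix")
  out <- data.frame(gene_id = names(d)[ord], degree = as.integer(d[ord]),
                    stringsAsFactors = FALSE)
  head(out, top)
}

#' Edge density
#'
#' Edges divided by the maximal number of possible edges `n(n-1)/2` for `n`
#' nodes.
#'
#' @param net A `grn_network`.
#' @return Density in \[0, 1\].
#' @export
edge_density <- function(net) {
  stopifnot(inherits(net, "grn_network"))
  n <- length(net$nodes)
  if (n < 2L) return(0)
  nrow(net$edges) / (n * (n - 1) / 2)
}

#' Maximum-likelihood power-law exponent of a degree sequence
#'
#' Fixed-`xmin` estimate using the continuous approximation for discrete
#' data, `alpha = 1 + n / sum(log(d_i / (xmin - 0.5)))` over degrees
#' `d_i >= xmin`.
#'
#' @param degrees Integer degree sequence.
#' @param xmin Lower cutoff of the power-law regime (default 1).
#' @return Estimated exponent.
#' @export
powerlaw_exponent <- function(degrees, xmin = 1L) {
  d <- degrees[degrees >= xmin]
  if (length(d) < 50L) stop("need >= 50 degrees at or above xmin")
  if (length(unique(d)) == 1L) stop("all degrees equal: exponent undefined")
  1 + length(d) / sum(log(d / (xmin - 0.5)))
}

#' Giant connected component
#'
#' Induced subnetwork on the largest connected vertex set; among equally
#' large components the one containing the lexicographically smallest member
#' wins.
#'
#' @param net A `grn_network`.
#' @return A `grn_network` restricted to the giant component.
#' @export
giant_component <- function(net) {
  stopifnot(inherits(net, "grn_network"))
  if (!length(net$nodes)) stop("empty network")
  g <- as_igraph(net)
  comp <- igraph::components(g)
  sizes <- comp$csize
  cands <- which(sizes == max(sizes))
  if (length(cands) > 1L) {
    firsts <- vapply(cands, function(cc) {
      min(igraph::V(g)$name[comp$membership == cc])
    }, character(1))
    cands <- cands[order(firsts)][1]
  }
  keep_nodes <- sort(igraph::V(g)$name[comp$membership == cands[1]])
  sel <- net$edges$gene_a %in% keep_nodes & net$edges$gene_b %in% keep_nodes
  grn_network(keep_nodes, net$edges[sel, , drop = FALSE], B = net$B)
}

#' Average shortest path length on the giant component
#'
#' Mean pairwise breadth-first-search distance (edges have unit length, so
#' this equals the Dijkstra distance on an unweighted graph) over node pairs
#' of the giant connected component. Exact for up to `max_exact` nodes;
#' above that, a seeded uniform sample of node pairs estimates the mean.
#'
#' @param net A `grn_network`.
#' @param max_exact Node count up to which all pairs are enumerated.
#' @param n_pairs Number of sampled pairs in the large-graph regime.
#' @param seed Seed for pair sampling.
#' @return Mean shortest-path length.
#' @export
avg_shortest_path <- function(net, max_exact = 2000L, n_pairs = 10000L,
                              seed = 1L) {
  gcc <- giant_component(net)
  if (length(gcc$nodes) < 2L) stop("giant component has fewer than 2 nodes")
  g <- as_igraph(gcc)
  if (length(gcc$nodes) <= max_exact) {
    return(igraph::mean_distance(g, directed = FALSE))
  }
  nv <- length(gcc$nodes)
  with_seed(seed, {
    i <- sample.int(nv, n_pairs, replace = TRUE)
    j <- sample.int(nv, n_pairs, replace = TRUE)
    clash <- i == j
    while (any(clash)) {
      j[clash] <- sample.int(nv, sum(clash), replace = TRUE)
      clash <- i == j
    }
    src <- sort(unique(i))
    dmat <- igraph::distances(g, v = src, to = igraph::V(g))
    mean(dmat[cbind(match(i, src), j)])
  })
}

#' Degree-rank correlation between two networks
#'
#' Spearman correlation of the degree ranks over the genes shared by both
#' networks; used to ask whether two inferred networks agree on which genes
#' are central even when their edge sets differ.
#'
#' @param net_a,net_b `grn_network` objects.
#' @return Rank correlation coefficient in \[-1, 1\].
#' @export
degree_rank_correlation <- function(net_a, net_b) {
  shared <- intersect(net_a$nodes, net_b$nodes)
  if (length(shared) < 3L) stop("fewer than 3 shared genes")
  da <- degree_centrality(net_a)[shared]
  db <- degree_centrality(net_b)[shared]
  cor(rank(da), rank(db))
}

#' Structural summary of a network
#'
#' @param net A `grn_network`.
#' @param xmin `xmin` for the power-law fit (degrees below it are ignored).
#' @param path_seed Seed for sampled path lengths on large graphs.
#' @return List with `n_nodes`, `n_edges`, `density`, `gcc_size`,
#'   `powerlaw_alpha` (NA when the fit preconditions fail),
#'   `avg_path_length`, and the `degree` table.
#' @export
network_summary <- function(net, xmin = 1L, path_seed = 1L) {
  deg <- degree_centrality(net)
  gcc <- giant_component(net)
  alpha <- tryCatch(powerlaw_exponent(deg[deg > 0], xmin = xmin),
                    error = function(e) NA_real_)
  apl <- if (length(gcc$nodes) >= 2L) {
    avg_shortest_path(net, seed = path_seed)
  } else {
    NA_real_
  }
  list(n_nodes = length(net$nodes), n_edges = nrow(net$edges),
       density = edge_density(net), gcc_size = length(gcc$nodes),
       powerlaw_alpha = alpha, avg_path_length = apl, degree = deg)
}
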