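#' Generate a planted scale-free dependency network
#'
#' Draws a degree sequence from a truncated discrete power law
#' (P(d) proportional to d^-exponent on `dmin..dmax`), realizes it with a
#' configuration model, and removes self-loops and multi-edges. Inferred
#' regulatory networks typically show degree exponents near 4, which
#' motivates the default. The minimum degree defaults to 2 so that the
#' realized graph has a giant component covering >= 90% of the genes (with
#' minimum degree 1 a power law this steep falls below the Molloy-Reed
#' percolation threshold). Each edge carries a dependency strength on the
#' partial-correlation scale, drawn uniformly from `strength_range`.
#'
#' @param p Number of genes (>= 20).
#' @param exponent Power-law exponent (> 2); default 4.
#' @param seed Integer seed; output is a pure function of the arguments.
#' @param dmin,dmax Degree truncation bounds (`dmax` defaults to
#'   `round(p^0.6)`).
#' @param strength_range Range of absolute edge strengths.
#' @param max_retries Attempts at drawing a realizable sequence whose giant
#'   component covers >= 90% of nodes.
#' @return List of class `planted_grn`: `nodes`, `edges` (data frame
#'   `gene_a`, `gene_b`, `strength`), `target_exponent`, `seed`.
#' @export
make_planted_grn <- function(p, exponent = 4.0, seed = 1L, dmin = 2L,
                             dmax = NULL, strength_range = c(0.25, 0.4),
                             max_retries = 50L) {
  if (p < 20L) stop("p must be >= 20")
  if (exponent <= 2) stop("exponent must be > 2")
  if (is.null(dmax)) dmax <- max(dmin + 1L, round(p^0.6))
  nodes <- sprintf("g%04d", seq_len(p))
  degs_support <- dmin:dmax
  prob <- degs_support^(-exponent)
  for (attempt in seq_len(max_retries)) {
    res <- with_seed(child_seed(seed, attempt), {
      degs <- sample(degs_support, p, replace = TRUE, prob = prob)
      if (sum(degs) %% 2L == 1L) degs[1] <- degs[1] + 1L
      g <- try(igraph::sample_degseq(degs, method = "configuration"),
               silent = TRUE)
      if (inherits(g, "try-error")) return(NULL)
      g <- igraph::simplify(g)
      comp <- igraph::components(g)
      if (max(comp$csize) < 0.9 * p) return(NULL)
      el <- igraph::as_edgelist(g, names = FALSE)
      strength <- runif(nrow(el), strength_range[1], strength_range[2])
      list(el = el, strength = strength)
    })
    if (!is.null(res)) {
      a <- nodes[pmin(res$el[, 1], res$el[, 2])]
      b <- nodes[pmax(res$el[, 1], res$el[, 2])]
      ord <- order(a, b, method = "radix")
      edges <- data.frame(gene_a = a[ord], gene_b = b[ord],
                          strength = res$strength[ord],
                          stringsAsFactors = FALSE)
      return(structure(list(nodes = nodes, edges = edges,
                            target_exponent = exponent, seed = as.integer(seed)),
                       class = "planted_grn"))
    }
  }
  stop("could not realize a degree sequence with a >=90% giant component after ",
       max_retries, " attempts")
}

#' @export
print.planted_grn <- function(x, ...) {
  cat(sprintf("planted_grn: %d genes, %d edges, target exponent %.2f\n",
              length(x$nodes), nrow(x$edges), x$target_exponent))
  invisible(x)
}

# Truth as a grn_network (for comparisons against inferred networks).
#' Convert a planted network to a `grn_network`
#' @param truth A `planted_grn`.
#' @return A `grn_network` with unit weights.
#' @export
truth_network <- function(truth) {
  stopifnot(inherits(truth, "planted_grn"))
  grn_network(truth$nodes,
              data.frame(gene_a = truth$edges$gene_a,
                         gene_b = truth$edges$gene_b,
                         ecr = 1, pvalue_adj = NA_real_,
                         stringsAsFactors = FALSE),
              B = 1L)
}

# Precision matrix of the Gaussian graphical model: -strength on edges,
# diagonal = row sum of absolute off-diagonals + margin (diagonal dominance
# guarantees positive definiteness).
planted_precision <- function(truth, margin = 0.1) {
  p <- length(truth$nodes)
  omega <- matrix(0, p, p, dimnames = list(truth$nodes, truth$nodes))
  ia <- match(truth$edges$gene_a, truth$nodes)
  ib <- match(truth$edges$gene_b, truth$nodes)
  omega[cbind(ia, ib)] <- -truth$edges$strength
  omega[cbind(ib, ia)] <- -truth$edges$strength
  diag(omega) <- rowSums(abs(omega)) + margin
  omega
}

#' Simulate expression data from a planted network
#'
#' Latent profiles are drawn from the Gaussian graphical model whose
#' precision matrix has `-strength` at the planted edges and a diagonally
#' dominant diagonal (row sum of absolute off-diagonals plus a margin of
#' 0.1), so the planted edges are the strongest pairwise dependencies.
#' The observation layer emulates the two platform families:
#' `rnaseq` maps the latent value z to a count `round(exp(0.7 z + 4))` and
#' returns `log1p` of the counts (log-scale normalized counts); `array` adds
#' Gaussian measurement noise with standard deviation `noise_sd`
#' (log-intensity scale).
#'
#' @param truth A `planted_grn`.
#' @param n Number of samples (>= 10); default 180, the scale of typical
#'   tumor expression cohorts.
#' @param platform `"rnaseq"` or `"array"`.
#' @param noise_sd Measurement noise SD for the array platform.
#' @param seed Integer seed.
#' @return Expression matrix (genes x samples) with gene/sample dimnames.
#' @export
simulate_expression <- function(truth, n = 180L, platform = c("rnaseq", "array"),
                                noise_sd = 0.1, seed = 1L) {
  platform <- match.arg(platform)
  stopifnot(inherits(truth, "planted_grn"))
  if (n < 10L) stop("n must be >= 10")
  p <- length(truth$nodes)
  omega <- planted_precision(truth)
  # Sigma = Omega^{-1}; draw z ~ N(0, Sigma) via the Cholesky factor of Omega:
  # if Omega = L L', then z = (L')^{-1} e with e ~ N(0, I) has cov Omega^{-1}.
  ch <- chol(omega)
  z <- with_seed(child_seed(seed, 1L), {
    e <- matrix(rnorm(p * n), nrow = p)
    backsolve(ch, e)
  })
  x <- if (platform == "rnaseq") {
    counts <- round(exp(0.7 * z + 4))
    log1p(counts)
  } else {
    noise <- with_seed(child_seed(seed, 2L),
                       matrix(rnorm(p * n, sd = noise_sd), nrow = p))
    z + noise
  }
  dimnames(x) <- list(truth$nodes, sprintf("s%03d", seq_len(n)))
  x
}

#' Plant connected gene sets and matched null sets
#'
#' True sets are vertex sets of connected subgraphs grown by breadth-first
#' search from random start nodes in the giant component (the signal a
#' gene-pair enrichment analysis must detect); null sets are uniform random
#' gene samples of matched sizes.
#'
#' @param truth A `planted_grn`.
#' @param k_true,k_null Numbers of true and null sets.
#' @param size_range Integer range of set sizes.
#' @param seed Integer seed.
#' @return List of two `gene_set_collection`s: `genesets_true`,
#'   `genesets_null`.
#' @export
plant_gene_sets <- function(truth, k_true = 10L, k_null = 10L,
                            size_range = c(5L, 10L), seed = 1L) {
  stopifnot(inherits(truth, "planted_grn"))
  g <- igraph::graph_from_data_frame(
    truth$edges[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = truth$nodes))
  comp <- igraph::components(g)
  giant <- which(comp$membership == which.max(comp$csize))
  if (max(size_range) > length(giant)) {
    stop("size_range exceeds the giant component")
  }
  with_seed(child_seed(seed, 3L), {
    sizes_true <- if (k_true > 0) sample(seq(size_range[1], size_range[2]),
                                         k_true, replace = TRUE) else integer()
    # sets are grown disjointly (BFS restricted to still-unused genes) so
    # each planted signal, and its genomic co-location, is well defined
    used <- character()
    true_sets <- lapply(sizes_true, function(sz) {
      for (try in 1:50) {
        avail <- setdiff(igraph::V(g)$name[giant], used)
        sub <- igraph::induced_subgraph(g, avail)
        comp <- igraph::components(sub)
        ok <- which(comp$csize >= sz)
        if (!length(ok)) next
        cmp <- if (length(ok) == 1L) ok else sample(ok, 1)
        cand <- which(comp$membership == cmp)
        start <- if (length(cand) == 1L) cand else sample(cand, 1)
        ord <- igraph::bfs(sub, root = start, order = TRUE)$order
        members <- igraph::V(sub)$name[ord[seq_len(sz)]]
        used <<- c(used, members)
        return(members)
      }
      stop("could not grow a disjoint connected set of size ", sz)
    })
    names(true_sets) <- sprintf("true_%02d", seq_along(true_sets))
    sizes_null <- if (k_null > 0) sizes_true[((seq_len(k_null) - 1L) %% max(1L, k_true)) + 1L]
                  else integer()
    if (k_true == 0L && k_null > 0L) {
      sizes_null <- sample(seq(size_range[1], size_range[2]), k_null, replace = TRUE)
    }
    null_sets <- lapply(sizes_null, function(sz) sample(truth$nodes, sz))
    names(null_sets) <- sprintf("null_%02d", seq_along(null_sets))
    list(
      genesets_true = gene_set_collection(
        true_sets, kind = "functional",
        description = setNames(rep("planted connected subgraph", length(true_sets)),
                               names(true_sets))),
      genesets_null = gene_set_collection(
        null_sets, kind = "functional",
        description = setNames(rep("uniform random set", length(null_sets)),
                               names(null_sets)))
    )
  })
}

#' Lay genes on synthetic chromosomes
#'
#' Genes are placed with a fixed inter-gene spacing (default 100 kb, the
#' scale at which co-expressed gene clusters extend over about one 1 Mb
#' window). A fraction of the true sets is made chromosomally co-located:
#' their members are placed contiguously starting at a 1 Mb window boundary,
#' with the spacing shrunk if needed so the whole set fits inside one window;
#' a >= 1 window gap separates each block from the following genes. All
#' remaining genes are shuffled and laid out sequentially.
#'
#' @param truth A `planted_grn`.
#' @param genesets_true The planted `gene_set_collection` (may be empty).
#' @param colocate_fraction Fraction of true sets to co-locate.
#' @param spacing_bp Inter-gene spacing in bp.
#' @param seed Integer seed.
#' @param genes_per_chrom Genes per synthetic chromosome.
#' @param window_bp Window size the co-located blocks must fit in.
#' @return Annotation data frame (`gene_id`, `chrom`, `start`, `end`) with
#'   attribute `colocated_sets` naming the sets placed contiguously.
#' @export
plant_annotation <- function(truth, genesets_true, colocate_fraction = 0.5,
                             spacing_bp = 100000L, seed = 1L,
                             genes_per_chrom = 100L, window_bp = 1000000L) {
  stopifnot(inherits(truth, "planted_grn"))
  sets <- genesets_true$sets
  n_coloc <- round(colocate_fraction * length(sets))
  coloc_names <- if (n_coloc > 0) names(sets)[seq_len(n_coloc)] else character()
  # co-located members must be unique across blocks; overlapping members stay
  # with the first block that claimed them
  placed <- character()
  blocks <- list()
  for (nm in coloc_names) {
    members <- setdiff(sets[[nm]], placed)
    if (length(members) < 2L) next
    blocks[[nm]] <- members
    placed <- c(placed, members)
  }
  rest <- setdiff(truth$nodes, placed)
  rest <- with_seed(child_seed(seed, 4L), sample(rest))
  gene_len <- 1000L

  chrom_i <- 1L; pos <- 0; n_on_chrom <- 0L
  rows <- vector("list", length(truth$nodes)); ri <- 0L
  advance_chrom <- function() {
    chrom_i <<- chrom_i + 1L; pos <<- 0; n_on_chrom <<- 0L
  }
  emit <- function(gene, start) {
    ri <<- ri + 1L
    rows[[ri]] <<- data.frame(gene_id = gene, chrom = paste0("chr", chrom_i),
                              start = start, end = start + gene_len,
                              stringsAsFactors = FALSE)
    n_on_chrom <<- n_on_chrom + 1L
  }
  for (nm in names(blocks)) {
    members <- blocks[[nm]]
    if (n_on_chrom + length(members) > genes_per_chrom) advance_chrom()
    # align block to the next window boundary so it sits inside one window
    pos <- ceiling(pos / window_bp) * window_bp
    sp <- min(spacing_bp, (window_bp - gene_len - 1) %/% max(1L, length(members)))
    for (g in members) {
      emit(g, pos)
      pos <- pos + sp
    }
    # full-window gap keeps the block's windows free of unrelated genes
    pos <- (ceiling(pos / window_bp) + 1L) * window_bp
  }
  for (g in rest) {
    if (n_on_chrom >= genes_per_chrom) advance_chrom()
    emit(g, pos)
    pos <- pos + spacing_bp
  }
  ann <- do.call(rbind, rows[seq_len(ri)])
  ann <- ann[order(ann$gene_id), , drop = FALSE]
  rownames(ann) <- NULL
  check_annotation(ann)
  attr(ann, "colocated_sets") <- names(blocks)
  ann
}

#' Corrupt the true network into a noisy reference
#'
#' Stand-in for an external protein-interaction reference: removes a
#' `rewire_rate` fraction of the true edges and adds an equal number of
#' uniformly random non-edges, preserving the edge count.
#'
#' @param truth A `planted_grn`.
#' @param rewire_rate Fraction in \[0, 1\] of edges replaced.
#' @param seed Integer seed.
#' @return A `grn_network` over the same nodes.
#' @export
corrupt_reference <- function(truth, rewire_rate = 0.3, seed = 1L) {
  stopifnot(inherits(truth, "planted_grn"))
  if (rewire_rate < 0 || rewire_rate > 1) stop("rewire_rate must be in [0,1]")
  nodes <- truth$nodes
  true_keys <- paste(truth$edges$gene_a, truth$edges$gene_b, sep = "\r")
  n_edges <- length(true_keys)
  n_replace <- round(rewire_rate * n_edges)
  with_seed(child_seed(seed, 5L), {
    drop_idx <- if (n_replace > 0) sample.int(n_edges, n_replace) else integer()
    kept <- true_keys[setdiff(seq_len(n_edges), drop_idx)]
    new_keys <- character(0)
    existing <- c(true_keys)
    while (length(new_keys) < n_replace) {
      need <- n_replace - length(new_keys)
      a <- sample(nodes, 2L * need, replace = TRUE)
      b <- sample(nodes, 2L * need, replace = TRUE)
      ok <- a != b
      key <- paste(pmin(a, b), pmax(a, b), sep = "\r")[ok]
      key <- setdiff(unique(key), c(existing, new_keys))
      new_keys <- c(new_keys, head(key, need))
    }
    keys <- c(kept, new_keys)
    ab <- strsplit(keys, "\r", fixed = TRUE)
    edges <- data.frame(gene_a = vapply(ab, `[[`, character(1), 1L),
                        gene_b = vapply(ab, `[[`, character(1), 2L),
                        ecr = 1, pvalue_adj = NA_real_,
                        stringsAsFactors = FALSE)
    grn_network(nodes, edges, B = 1L)
  })
}

#' Generate a complete synthetic benchmark bundle
#'
#' Fans a single seed out to per-stage child seeds and produces everything
#' the pipeline consumes: planted network, expression matrix, true and null
#' gene sets, genomic annotation with co-located clusters, and a corrupted
#' reference network.
#'
#' @param p Genes (default 500). @param n Samples (default 180).
#' @param platform `"rnaseq"` or `"array"`.
#' @param exponent Degree power-law exponent of the planted network.
#' @param strength_range Edge strength range (partial-correlation scale).
#' @param k_true,k_null Numbers of planted and null gene sets.
#' @param size_range Gene-set size range.
#' @param colocate_fraction Fraction of true sets placed contiguously.
#' @param spacing_bp Inter-gene genomic spacing.
#' @param rewire_rate Reference corruption rate.
#' @param noise_sd Array measurement noise SD.
#' @param seed Integer master seed.
#' @return List of class `synthetic_bundle` with elements `truth`,
#'   `expression`, `genesets_true`, `genesets_null`, `annotation`,
#'   `reference_net`, `seed`.
#' @export
make_synthetic_bundle <- function(p = 500L, n = 180L, platform = "rnaseq",
                                  exponent = 4.0, strength_range = c(0.25, 0.4),
                                  k_true = 10L, k_null = 10L,
                                  size_range = c(5L, 10L),
                                  colocate_fraction = 0.5, spacing_bp = 100000L,
                                  rewire_rate = 0.3, noise_sd = 0.1, seed = 1L) {
  truth <- make_planted_grn(p, exponent = exponent, seed = child_seed(seed, 11L),
                            strength_range = strength_range)
  expr <- simulate_expression(truth, n = n, platform = platform,
                              noise_sd = noise_sd, seed = child_seed(seed, 12L))
  gs <- plant_gene_sets(truth, k_true = k_true, k_null = k_null,
                        size_range = size_range, seed = child_seed(seed, 13L))
  ann <- plant_annotation(truth, gs$genesets_true,
                          colocate_fraction = colocate_fraction,
                          spacing_bp = spacing_bp, seed = child_seed(seed, 14L))
  ref <- corrupt_reference(truth, rewire_rate = rewire_rate,
                           seed = child_seed(seed, 15L))
  structure(list(truth = truth, expression = expr,
                 genesets_true = gs$genesets_true,
                 genesets_null = gs$genesets_null,
                 annotation = ann, reference_net = ref,
                 seed = as.integer(seed)),
            class = "synthetic_bundle")
}
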