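# Restrict an edge table to pairs with both endpoints in `universe`.
restrict_edges <- function(net, universe) {
  e <- net$edges
  e[e$gene_a %in% universe & e$gene_b %in% universe, , drop = FALSE]
}

#' Edge overlap between two or three networks
#'
#' Shared edges over the union of edges, computed on the shared node
#' universe (node-set intersection). For three networks the triple
#' intersection over the triple union is reported.
#'
#' @param nets List of 2 or 3 `grn_network` objects.
#' @return List with `shared` (canonical shared edge data frame),
#'   `n_shared`, `n_union`, `shared_pct`.
#' @export
edge_overlap <- function(nets) {
  stopifnot(is.list(nets), length(nets) %in% c(2L, 3L),
            all(vapply(nets, inherits, logical(1), "grn_network")))
  universe <- Reduce(intersect, lapply(nets, `[[`, "nodes"))
  keysets <- lapply(nets, function(nt) edge_keys(restrict_edges(nt, universe)))
  shared_keys <- Reduce(intersect, keysets)
  union_keys <- Reduce(union, keysets)
  if (!length(union_keys)) stop("empty edge union on the shared universe")
  ab <- strsplit(sort(shared_keys), "\r", fixed = TRUE)
  shared <- data.frame(
    gene_a = vapply(ab, `[[`, character(1), 1L),
    gene_b = vapply(ab, `[[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
  list(shared = shared, n_shared = length(shared_keys),
       n_union = length(union_keys),
       shared_pct = length(shared_keys) / length(union_keys))
}

#' Hypergeometric test for shared edges between two networks
#'
#' Tests whether the number of edges shared by two networks exceeds random
#' expectation: population = all `C(u, 2)` gene pairs of the universe,
#' successes = edges of the first network, draws = edges of the second,
#' observed = shared edges. Reuses the gene-pair enrichment kernel
#' ([gpea_pvalue()]); the test is symmetric in the two networks.
#'
#' @param net_a,net_b `grn_network` objects.
#' @param universe Node universe (default: node-set intersection).
#' @return Upper-tail p-value.
#' @export
shared_edge_test <- function(net_a, net_b, universe = NULL) {
  if (is.null(universe)) universe <- intersect(net_a$nodes, net_b$nodes)
  u <- length(universe)
  N <- u * (u - 1) / 2
  ka <- edge_keys(restrict_edges(net_a, universe))
  kb <- edge_keys(restrict_edges(net_b, universe))
  if (length(ka) > N || length(kb) > N) stop("edge count exceeds the pair space")
  gpea_pvalue(k = length(intersect(ka, kb)), m_S = length(ka),
              n = length(kb), N = N)
}

#' Confusion metrics of a network against a reference
#'
#' Over all gene pairs of the comparison universe: TP = pairs that are edges
#' in both networks, FP = network-only, FN = reference-only, TN = the
#' remaining pairs. Precision `P = TP/(TP+FP)`, recall `R = TP/(TP+FN)` and
#' `F = 2PR/(P+R)` (0 by convention when `P + R = 0`). The universe defaults
#' to the node intersection so that coverage differences are not counted as
#' disagreement; pass the node union for a global-table style comparison.
#'
#' @param net,ref `grn_network` objects (network under test, reference).
#' @param universe Node universe (default: node-set intersection).
#' @return List of class `comparison_metrics`: `TP`, `FP`, `TN`, `FN`,
#'   `precision`, `recall`, `fscore`, `shared_pct`, `universe_size`.
#' @export
confusion_vs_reference <- function(net, ref, universe = NULL) {
  if (is.null(universe)) universe <- intersect(net$nodes, ref$nodes)
  u <- length(universe)
  if (u < 2L) stop("comparison universe has fewer than 2 genes")
  pairs_total <- u * (u - 1) / 2
  kn <- edge_keys(restrict_edges(net, universe))
  kr <- edge_keys(restrict_edges(ref, universe))
  TP <- length(intersect(kn, kr))
  FP <- length(kn) - TP
  FN <- length(kr) - TP
  TN <- pairs_total - TP - FP - FN
  precision <- if (TP + FP > 0) TP / (TP + FP) else 0
  recall <- if (TP + FN > 0) TP / (TP + FN) else 0
  fscore <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  n_union <- length(union(kn, kr))
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 precision = precision, recall = recall, fscore = fscore,
                 shared_pct = if (n_union > 0) TP / n_union else 0,
                 universe_size = u),
            class = "comparison_metrics")
}

#' @export
print.comparison_metrics <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d FN=%d TN=%.0f | P=%.3f R=%.3f F=%.3f\n",
              x$TP, x$FP, x$FN, x$TN, x$precision, x$recall, x$fscore))
  invisible(x)
}

# Induced subnetwork of `net` on `members`.
induced_subnetwork <- function(net, members) {
  members <- intersect(members, net$nodes)
  grn_network(members, restrict_edges(net, members), B = net$B)
}

#' Per-gene-set subnetwork F-scores against a reference
#'
#' For each gene set, the induced subgraphs of the network and of the
#' reference on the set's members are compared with
#' [confusion_vs_reference()]. Sets whose reference induced subgraph has no
#' edges are skipped (a comparison against an empty reference subnetwork is
#' uninformative) and counted in the `n_skipped` attribute.
#'
#' @param net,ref `grn_network` objects.
#' @param sets A `gene_set_collection`.
#' @return Data frame with one row per compared set (`set_name`, `p_S`,
#'   `TP`, `FP`, `FN`, `precision`, `recall`, `fscore`); skipped set names in
#'   attribute `skipped`.
#' @export
subnetwork_fscores <- function(net, ref, sets) {
  stopifnot(inherits(sets, "gene_set_collection"))
  rows <- list(); skipped <- character()
  for (nm in names(sets$sets)) {
    members <- sets$sets[[nm]]
    sub_ref <- induced_subnetwork(ref, members)
    if (nrow(sub_ref$edges) == 0L) {
      skipped <- c(skipped, nm)
      next
    }
    sub_net <- induced_subnetwork(net, members)
    universe <- intersect(intersect(members, net$nodes), ref$nodes)
    if (length(universe) < 2L) {
      skipped <- c(skipped, nm)
      next
    }
    cm <- confusion_vs_reference(sub_net, sub_ref, universe = universe)
    rows[[nm]] <- data.frame(set_name = nm, p_S = length(universe),
                             TP = cm$TP, FP = cm$FP, FN = cm$FN,
                             precision = cm$precision, recall = cm$recall,
                             fscore = cm$fscore, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(set_name = character(), p_S = integer(), TP = integer(),
               FP = integer(), FN = integer(), precision = numeric(),
               recall = numeric(), fscore = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "n_skipped") <- length(skipped)
  out
}

#' Gene-label-randomized baseline F-score distribution
#'
#' Repeats the per-set comparison of [subnetwork_fscores()] against versions
#' of the reference whose node labels have been uniformly permuted,
#' destroying any specific agreement while preserving the reference's
#' topology. Gives the chance level the true F-scores must exceed.
#'
#' @param net,ref `grn_network` objects.
#' @param sets A `gene_set_collection`.
#' @param reps Number of label permutations (default 25).
#' @param seed Integer seed (the baseline is deterministic given it).
#' @param perm_fn Permutation hook for testing: a function mapping the node
#'   vector to its permuted order (default: uniform random shuffle). The
#'   identity function reproduces the unrandomized comparison.
#' @return List with `per_rep` (list of per-set F tables), `pooled`
#'   (numeric vector of all baseline F-scores), `mean_f` (their mean), and
#'   `per_set_mean` (mean baseline F per set over reps).
#' @export
randomized_label_baseline <- function(net, ref, sets, reps = 25L, seed = 1L,
                                      perm_fn = NULL) {
  if (reps < 1L) stop("reps must be >= 1")
  per_rep <- vector("list", reps)
  for (r in seq_len(reps)) {
    new_labels <- if (is.null(perm_fn)) {
      with_seed(child_seed(seed, 100L + r), sample(ref$nodes))
    } else {
      perm_fn(ref$nodes)
    }
    map <- setNames(new_labels, ref$nodes)
    redges <- ref$edges
    redges$gene_a <- unname(map[redges$gene_a])
    redges$gene_b <- unname(map[redges$gene_b])
    rref <- grn_network(sort(new_labels), redges, B = ref$B)
    per_rep[[r]] <- subnetwork_fscores(net, rref, sets)
  }
  pooled <- unlist(lapply(per_rep, `[[`, "fscore"), use.names = FALSE)
  all_sets <- unique(unlist(lapply(per_rep, `[[`, "set_name")))
  per_set_mean <- vapply(all_sets, function(nm) {
    vals <- unlist(lapply(per_rep, function(df) df$fscore[df$set_name == nm]))
    mean(vals)
  }, numeric(1))
  list(per_rep = per_rep, pooled = pooled,
       mean_f = if (length(pooled)) mean(pooled) else NA_real_,
       per_set_mean = per_set_mean)
}
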