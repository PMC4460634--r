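# Replicated synthetic benchmark runs shared by the planted-signal-recovery
# and inference-ordering acceptance tests. Computed lazily once per session
# and cached, since the ensemble inference dominates the suite's runtime.

.bundle_cache <- new.env(parent = emptyenv())

benchmark_replicates <- function(n_reps = 10L, p = 500L, n = 180L, B = 50L,
                                 base_seed = 20260L, n_draws = 25000L) {
  key <- sprintf("reps_%d_%d_%d_%d_%d", n_reps, p, n, B, base_seed)
  if (!is.null(.bundle_cache[[key]])) return(.bundle_cache[[key]])
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    seed <- base_seed + r
    bundle <- make_synthetic_bundle(p = p, n = n, seed = seed)
    net <- bc3net(bundle$expression, B = B, seed = seed, n_draws = n_draws)
    sets_all <- gene_set_collection(
      c(bundle$genesets_true$sets, bundle$genesets_null$sets), "functional")
    gpea <- run_gpea(net, filter_collection(sets_all, min_genes = 3L,
                                            universe = net$nodes),
                     alpha = 0.001)
    windows <- window_gene_sets(bundle$annotation)
    gpea_win <- run_gpea(net, filter_collection(windows, min_genes = 3L,
                                                universe = net$nodes),
                         alpha = 0.001)
    truth <- truth_network(bundle$truth)
    cm <- confusion_vs_reference(net, truth)
    # global label-randomized baseline: permute the truth's gene labels and
    # recompute the global F-score
    base_f <- vapply(seq_len(25L), function(i) {
      set.seed(seed * 100 + i)
      perm <- sample(truth$nodes)
      map <- setNames(perm, truth$nodes)
      redges <- truth$edges
      redges$gene_a <- unname(map[redges$gene_a])
      redges$gene_b <- unname(map[redges$gene_b])
      rtruth <- grn_network(sort(perm), redges)
      confusion_vs_reference(net, rtruth)$fscore
    }, numeric(1))
    reps[[r]] <- list(bundle = bundle, net = net, gpea = gpea,
                      gpea_win = gpea_win, fscore = cm$fscore,
                      baseline_f = base_f)
  }
  .bundle_cache[[key]] <- reps
  reps
}
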