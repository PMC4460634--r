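# Structural characterization of the inferred networks: degree hubs, edge
# density, giant component, power-law exponent of the degree distribution,
# average shortest path, and the pairwise/triple edge overlaps between the
# inference methods.
source("analysis/00_config.R")

nets <- list(bc3net = read_network(file.path(outdir, "net_bc3net.tsv")),
             c3net = read_network(file.path(outdir, "net_c3net.tsv")),
             abscorr = read_network(file.path(outdir, "net_abscorr.tsv")))

rows <- lapply(names(nets), function(nm) {
  s <- network_summary(nets[[nm]], xmin = 3L, path_seed = cfg$seed)
  message(sprintf(
    "%s: %d nodes, %d edges, density %.4g, gcc %d, alpha %.2f, path %.2f",
    nm, s$n_nodes, s$n_edges, s$density, s$gcc_size, s$powerlaw_alpha,
    s$avg_path_length))
  data.frame(network = nm, n_nodes = s$n_nodes, n_edges = s$n_edges,
             density = s$density, gcc_size = s$gcc_size,
             powerlaw_alpha = s$powerlaw_alpha,
             avg_path_length = s$avg_path_length)
})
write.table(do.call(rbind, rows), file.path(outdir, "structure_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

hubs <- hub_table(nets$bc3net, top = 25)
write.table(hubs, file.path(outdir, "hubs_bc3net.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("top hub: %s (degree %d)", hubs$gene_id[1], hubs$degree[1]))

# do the methods agree on which genes are central, even where edges differ?
for (pr in combn(names(nets), 2, simplify = FALSE)) {
  message(sprintf("degree-rank correlation %s/%s: %.2f", pr[1], pr[2],
                  degree_rank_correlation(nets[[pr[1]]], nets[[pr[2]]])))
}

# edge overlap across methods: pairwise and triple, plus the shared-edge test
pairs <- combn(names(nets), 2, simplify = FALSE)
ov_rows <- lapply(pairs, function(pr) {
  ov <- edge_overlap(nets[pr])
  p <- shared_edge_test(nets[[pr[1]]], nets[[pr[2]]])
  message(sprintf("overlap %s/%s: %d shared / %d union (%.1f%%), p = %.3g",
                  pr[1], pr[2], ov$n_shared, ov$n_union,
                  100 * ov$shared_pct, p))
  data.frame(net_a = pr[1], net_b = pr[2], n_shared = ov$n_shared,
             n_union = ov$n_union, shared_pct = ov$shared_pct, pvalue = p)
})
trip <- edge_overlap(nets)
message(sprintf("triple overlap: %d shared / %d union (%.2f%%)",
                trip$n_shared, trip$n_union, 100 * trip$shared_pct))
ov_df <- do.call(rbind, ov_rows)
ov_df <- rbind(ov_df, data.frame(net_a = "all3", net_b = "all3",
                                 n_shared = trip$n_shared,
                                 n_union = trip$n_union,
                                 shared_pct = trip$shared_pct,
                                 pvalue = NA))
write.table(ov_df, file.path(outdir, "edge_overlap.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
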