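# Quantify inference performance: confusion metrics and F-score of every
# inferred network against the planted truth and against the corrupted
# reference, per-gene-set subnetwork F-scores, and the gene-label-randomized
# baseline that calibrates them.
source("analysis/00_config.R")

truth <- read_network(file.path(outdir, "truth.tsv"))
ref <- read_network(file.path(outdir, "reference.tsv"))
truesets <- read_gmt(file.path(outdir, "sets_true.gmt"))
nets <- list(bc3net = read_network(file.path(outdir, "net_bc3net.tsv")),
             c3net = read_network(file.path(outdir, "net_c3net.tsv")),
             abscorr = read_network(file.path(outdir, "net_abscorr.tsv")),
             clr = read_network(file.path(outdir, "net_clr.tsv")))

rows <- lapply(names(nets), function(nm) {
  ct <- confusion_vs_reference(nets[[nm]], truth, universe = truth$nodes)
  cr <- confusion_vs_reference(nets[[nm]], ref, universe = truth$nodes)
  message(sprintf("%s: F=%.3f (truth)  F=%.3f (reference)  P=%.3f R=%.3f",
                  nm, ct$fscore, cr$fscore, ct$precision, ct$recall))
  data.frame(network = nm, f_truth = ct$fscore, precision = ct$precision,
             recall = ct$recall, f_reference = cr$fscore)
})
write.table(do.call(rbind, rows), file.path(outdir, "compare_global.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# per-set subnetwork F-scores against the reference, with the 25-fold
# label-randomized baseline
sf <- subnetwork_fscores(nets$bc3net, ref, truesets)
write.table(sf, file.path(outdir, "compare_sets.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
base <- randomized_label_baseline(nets$bc3net, ref, truesets, reps = 25,
                                  seed = cfg$seed)
message(sprintf(
  "subnetwork F: mean %.3f over %d sets (%d skipped); randomized baseline %.4f",
  mean(sf$fscore), nrow(sf), attr(sf, "n_skipped"), base$mean_f))
base_df <- data.frame(set_name = names(base$per_set_mean),
                      baseline_mean_f = unname(base$per_set_mean))
write.table(base_df, file.path(outdir, "compare_baseline.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
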