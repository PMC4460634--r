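# Build the gene-set collections the enrichment stage consumes: 1 Mb genomic
# windows tiled every 500 kb over the synthetic chromosomes, plus the planted
# functional sets and their size-matched null sets, all filtered against the
# inferred network's gene universe.
source("analysis/00_config.R")

ann <- read_annotation(file.path(outdir, "annotation.tsv"))
net <- read_network(file.path(outdir, "net_bc3net.tsv"))
universe <- sort(unique(c(net$edges$gene_a, net$edges$gene_b)))

windows <- window_gene_sets(ann, window_bp = 1e6, step_bp = 5e5, min_genes = 3)
message(sprintf("windows: %d sets of >= 3 genes over %d chromosomes",
                length(windows$sets), length(unique(ann$chrom))))
write_gmt(windows, file.path(outdir, "windows.gmt"))

truesets <- read_gmt(file.path(outdir, "sets_true.gmt"))
nullsets <- read_gmt(file.path(outdir, "sets_null.gmt"))
combined <- gene_set_collection(c(truesets$sets, nullsets$sets), "functional",
                                c(truesets$description, nullsets$description))
filtered <- filter_collection(combined, min_genes = 3, universe = universe)
message(sprintf("functional sets: %d kept after universe filter (%d dropped)",
                length(filtered$sets), attr(filtered, "n_dropped")))
write_gmt(filtered, file.path(outdir, "sets_filtered.gmt"))
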