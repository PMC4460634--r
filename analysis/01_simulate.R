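# Generate the synthetic benchmark: a planted scale-free dependency network
# realized as a Gaussian graphical model, RNAseq-like expression for n
# samples, planted connected gene sets (half of them chromosomally
# co-located), and a 30%-rewired reference network standing in for an
# external interaction database.
source("analysis/00_config.R")

bundle <- make_synthetic_bundle(p = cfg$p, n = cfg$n, seed = cfg$seed)

write_expression(bundle$expression, file.path(outdir, "expression.tsv"))
write_network(truth_network(bundle$truth), file.path(outdir, "truth.tsv"))
write_annotation(bundle$annotation, file.path(outdir, "annotation.tsv"))
write_gmt(bundle$genesets_true, file.path(outdir, "sets_true.gmt"))
write_gmt(bundle$genesets_null, file.path(outdir, "sets_null.gmt"))
write_network(bundle$reference_net, file.path(outdir, "reference.tsv"))

tn <- truth_network(bundle$truth)
deg <- degree_centrality(tn)
message(sprintf("planted network: %d genes, %d edges, max degree %d",
                cfg$p, nrow(tn$edges), max(deg)))
message(sprintf("giant component: %d genes (%.1f%%)",
                length(giant_component(tn)$nodes),
                100 * length(giant_component(tn)$nodes) / cfg$p))
message(sprintf("degree power-law exponent (xmin = 3): %.2f",
                powerlaw_exponent(deg[deg > 0], xmin = 3)))
message(sprintf("co-located gene sets: %s",
                paste(attr(bundle$annotation, "colocated_sets"),
                      collapse = ", ")))
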