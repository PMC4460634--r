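# Infer networks from the simulated expression matrix: the BC3Net bootstrap
# ensemble (the primary method), a single C3Net run, and the two
# hard-threshold relevance-network baselines (absolute correlation and CLR)
# at a matched edge count.
source("analysis/00_config.R")

expr <- drop_zero_sd_genes(read_expression(file.path(outdir, "expression.tsv")))
message(sprintf("expression: %d genes x %d samples after zero-SD filtering",
                nrow(expr), ncol(expr)))

pool <- null_mi_pool(expr, n_draws = cfg$n_draws,
                     seed = cfg$seed)
net_bc3 <- bc3net(expr, B = cfg$B, seed = cfg$seed, pool = pool)
write_network(net_bc3, file.path(outdir, "net_bc3net.tsv"))
message(sprintf("bc3net: %d edges (ECR range %.2f-%.2f)",
                nrow(net_bc3$edges), min(net_bc3$edges$ecr),
                max(net_bc3$edges$ecr)))

net_c3 <- c3net(expr, pool = pool)
write_network(net_c3, file.path(outdir, "net_c3net.tsv"))
message(sprintf("c3net: %d edges", nrow(net_c3$edges)))

# relevance baselines at the percentile that matches bc3net's edge count
n_pairs <- choose(nrow(expr), 2)
pct <- 1 - nrow(net_bc3$edges) / n_pairs
for (method in c("abscorr", "clr")) {
  net <- relevance_network(expr, method, percentile = pct)
  write_network(net, file.path(outdir, sprintf("net_%s.tsv", method)))
  message(sprintf("%s (percentile %.4f): %d edges", method, pct,
                  nrow(net$edges)))
}
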