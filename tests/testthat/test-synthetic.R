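test_that("planted network is a simple scale-free graph, deterministic in seed", {
  g1 <- make_planted_grn(100, exponent = 4.0, seed = 1)
  g2 <- make_planted_grn(100, exponent = 4.0, seed = 1)
  expect_identical(g1$edges, g2$edges)
  expect_true(all(g1$edges$gene_a < g1$edges$gene_b))
  expect_equal(anyDuplicated(paste(g1$edges$gene_a, g1$edges$gene_b)), 0L)
  deg <- degree_centrality(truth_network(g1))
  expect_lt(max(deg), 100 / 3)  # hubs, but far below the gene count
  expect_error(make_planted_grn(100, exponent = 1.5), "exponent")
  expect_error(make_planted_grn(10), "p must be")
  expect_true(all(abs(g1$edges$strength) >= 0.25 &
                  abs(g1$edges$strength) <= 0.4))
})

test_that("giant component covers >= 90% of genes", {
  for (seed in 1:3) {
    g <- make_planted_grn(200, seed = seed)
    gcc <- giant_component(truth_network(g))
    expect_gte(length(gcc$nodes), 0.9 * 200)
  }
})

test_that("degree power-law exponent is recovered at large p", {
  g <- make_planted_grn(1500, exponent = 4.0, seed = 2)
  deg <- degree_centrality(truth_network(g))
  # fit the tail: the continuous-approximation MLE is accurate above xmin ~ 3
  alpha <- powerlaw_exponent(deg[deg > 0], xmin = 3)
  expect_lt(abs(alpha - 4.0), 0.5)
})

test_that("simulated expression reflects the planted dependency structure", {
  truth <- make_planted_grn(40, seed = 5)
  x <- simulate_expression(truth, n = 200, platform = "array",
                           noise_sd = 0.05, seed = 9)
  expect_identical(x, simulate_expression(truth, n = 200, platform = "array",
                                          noise_sd = 0.05, seed = 9))
  rho <- cor(t(x))
  # planted edges show clearly nonzero correlation
  e <- truth$edges[1:5, ]
  for (i in seq_len(nrow(e))) {
    expect_gt(abs(rho[e$gene_a[i], e$gene_b[i]]), 3 / sqrt(200))
  }
  # node pairs in different components are independent
  g <- igraph::graph_from_data_frame(truth$edges[, 1:2], directed = FALSE,
                                     vertices = data.frame(name = truth$nodes))
  comp <- igraph::components(g)$membership
  pairs_checked <- 0
  for (a in truth$nodes) {
    for (b in truth$nodes) {
      if (a < b && comp[[a]] != comp[[b]] && pairs_checked < 10) {
        expect_lt(abs(rho[a, b]), 3 / sqrt(200))
        pairs_checked <- pairs_checked + 1
      }
    }
  }
  # rnaseq platform returns log1p of integer counts
  xr <- simulate_expression(truth, n = 50, platform = "rnaseq", seed = 3)
  expect_true(all(xr >= 0))
  expect_equal(round(expm1(xr)), expm1(xr), tolerance = 1e-9)
})

test_that("empirical covariance approaches the model covariance", {
  truth <- make_planted_grn(25, seed = 6)
  sigma <- solve(grngpea:::planted_precision(truth))
  x <- simulate_expression(truth, n = 5000, platform = "array",
                           noise_sd = 0, seed = 12)
  emp <- cov(t(x))
  # elementwise 5-standard-error band: Var(cov_ij) ~ (s_ii s_jj + s_ij^2)/n
  se <- sqrt((diag(sigma) %o% diag(sigma) + sigma^2) / 5000)
  expect_true(all(abs(emp - sigma) < 5 * se))
})

test_that("planted gene sets are connected subgraphs; null sets are diffuse", {
  truth <- make_planted_grn(150, seed = 3)
  gs <- plant_gene_sets(truth, k_true = 6, k_null = 6,
                        size_range = c(10, 10), seed = 4)
  tnet <- truth_network(truth)
  for (s in gs$genesets_true$sets) {
    sub <- grngpea:::induced_subnetwork(tnet, s)
    expect_gte(nrow(sub$edges), length(s) - 1)  # connected => >= size-1 edges
  }
  # null sets: expected induced edge count near density * m_S
  dens <- edge_density(tnet)
  m_S <- choose(10, 2)
  null_k <- vapply(gs$genesets_null$sets, function(s) {
    nrow(grngpea:::induced_subnetwork(tnet, s)$edges)
  }, integer(1))
  expect_lt(mean(null_k), dens * m_S + 3 * sqrt(dens * m_S) + 1)

  empty <- plant_gene_sets(truth, k_true = 0, k_null = 0, seed = 1)
  expect_equal(length(empty$genesets_true$sets), 0L)
  expect_identical(plant_gene_sets(truth, 3, 3, seed = 9),
                   plant_gene_sets(truth, 3, 3, seed = 9))
  expect_error(plant_gene_sets(truth, 1, 1, size_range = c(200, 300)),
               "giant component")
})

test_that("annotation co-locates the requested sets inside one window", {
  truth <- make_planted_grn(120, seed = 8)
  gs <- plant_gene_sets(truth, k_true = 4, k_null = 0,
                        size_range = c(8, 8), seed = 2)
  ann <- plant_annotation(truth, gs$genesets_true, colocate_fraction = 0.5,
                          seed = 3)
  expect_setequal(ann$gene_id, truth$nodes)
  coloc <- attr(ann, "colocated_sets")
  # up to half the sets are placed; overlapping sets may be absorbed by an
  # earlier block, so at least one distinct block must remain
  expect_gte(length(coloc), 1L)
  expect_lte(length(coloc), 2L)
  for (nm in coloc) {
    members <- gs$genesets_true$sets[[nm]]
    sub <- ann[ann$gene_id %in% members, ]
    expect_equal(length(unique(sub$chrom)), 1L)
    w <- floor(min(sub$start) / 1e6) * 1e6
    expect_true(all(sub$start >= w & sub$start < w + 1e6))
  }
  # positions strictly increasing per chromosome (in placement order)
  for (chr in unique(ann$chrom)) {
    st <- sort(ann$start[ann$chrom == chr])
    expect_true(all(diff(st) > 0))
  }
  ann0 <- plant_annotation(truth, gs$genesets_true, colocate_fraction = 0,
                           seed = 3)
  expect_equal(length(attr(ann0, "colocated_sets")), 0L)
})

test_that("reference corruption preserves edge count and is graded", {
  truth <- make_planted_grn(80, seed = 10)
  tnet <- truth_network(truth)
  ref0 <- corrupt_reference(truth, rewire_rate = 0, seed = 1)
  expect_equal(confusion_vs_reference(ref0, tnet)$fscore, 1)
  for (rate in c(0.2, 0.5, 1)) {
    ref <- corrupt_reference(truth, rewire_rate = rate, seed = 1)
    expect_equal(nrow(ref$edges), nrow(truth$edges))
  }
  ref1 <- corrupt_reference(truth, rewire_rate = 1, seed = 2)
  ov <- edge_overlap(list(ref1, tnet))
  # fully rewired: overlap near the random expectation (edge density scale)
  expect_lt(ov$shared_pct, 5 * edge_density(tnet) + 0.05)
  expect_error(corrupt_reference(truth, rewire_rate = 1.2), "rewire_rate")
})
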