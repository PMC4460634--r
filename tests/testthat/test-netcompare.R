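test_that("edge overlap on pairs and triples follows set arithmetic", {
  a <- toy_network(list(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "e"),
                        c("e", "f"), c("a", "f")))
  expect_equal(edge_overlap(list(a, a))$shared_pct, 1)

  b <- toy_network(list(c("a", "b"), c("b", "c"), c("a", "c"), c("d", "f"),
                        c("c", "e")), nodes = a$nodes)
  ov <- edge_overlap(list(a, b))
  expect_equal(ov$n_shared, 2L)       # a-b and b-c
  expect_equal(ov$n_union, 9L)        # 6 + 5 - 2
  expect_equal(ov$shared_pct, 2 / 9)

  disj <- toy_network(list(c("a", "c"), c("b", "d")), nodes = a$nodes)
  expect_equal(edge_overlap(list(a, disj))$shared_pct, 0)

  trip <- edge_overlap(list(a, b, toy_network(list(c("a", "b")), nodes = a$nodes)))
  expect_equal(trip$n_shared, 1L)
})

test_that("shared-edge test reuses the pair-enrichment kernel symmetrically", {
  u <- letters[1:8]
  net_a <- toy_network(list(c("a", "b"), c("c", "d"), c("e", "f")), nodes = u)
  net_b <- toy_network(list(c("a", "b"), c("c", "d"), c("g", "h"), c("b", "c")),
                       nodes = u)
  p_ab <- shared_edge_test(net_a, net_b)
  expect_equal(p_ab, shared_edge_test(net_b, net_a))
  expect_equal(p_ab, gpea_pvalue(k = 2, m_S = 3, n = 4, N = choose(8, 2)))

  # E_b subset of E_a: closed-form product tail for observing all draws shared
  sub <- toy_network(list(c("a", "b"), c("c", "d")), nodes = u)
  p_sub <- shared_edge_test(net_a, sub)
  N <- choose(8, 2)
  expect_equal(p_sub, choose(3, 2) / choose(N, 2) *
                 choose(N - 3, 0) / 1)  # C(3,2)C(25,0)/C(28,2)
  # no shared edges in sparse nets: p near 1
  expect_gt(shared_edge_test(net_a, toy_network(list(c("a", "h")), nodes = u)),
            0.6)
})

test_that("confusion metrics conserve the pair space and match formulas", {
  u <- letters[1:8]
  ref <- toy_network(list(c("a", "b"), c("c", "d"), c("e", "f"), c("g", "h")),
                     nodes = u)
  expect_equal(confusion_vs_reference(ref, ref)$fscore, 1)

  net <- toy_network(list(c("a", "b"), c("c", "d"), c("a", "c"), c("b", "d")),
                     nodes = u)
  cm <- confusion_vs_reference(net, ref)
  expect_equal(cm$TP, 2L)
  expect_equal(cm$FP, 2L)
  expect_equal(cm$FN, 2L)
  expect_equal(cm$precision, 0.5)
  expect_equal(cm$recall, 0.5)
  expect_equal(cm$fscore, 0.5)
  expect_equal(cm$TP + cm$FP + cm$FN + cm$TN, choose(8, 2))
  # harmonic mean never exceeds arithmetic mean
  expect_lte(cm$fscore, (cm$precision + cm$recall) / 2)

  empty <- grn_network(u)
  expect_equal(confusion_vs_reference(empty, ref)$fscore, 0)
})

test_that("per-set F-scores skip empty reference subnetworks and compose", {
  set.seed(19)
  truth <- make_planted_grn(60, seed = 3)
  net <- truth_network(truth)
  ref <- corrupt_reference(truth, rewire_rate = 0.4, seed = 5)
  gs <- plant_gene_sets(truth, k_true = 5, k_null = 3,
                        size_range = c(6, 9), seed = 7)
  sets <- gene_set_collection(c(gs$genesets_true$sets, gs$genesets_null$sets),
                              "functional")
  sf <- subnetwork_fscores(net, ref, sets)
  expect_true(nrow(sf) + attr(sf, "n_skipped") == length(sets$sets))
  for (i in seq_len(nrow(sf))) {
    members <- sets$sets[[sf$set_name[i]]]
    cm <- confusion_vs_reference(
      grngpea:::induced_subnetwork(net, members),
      grngpea:::induced_subnetwork(ref, members),
      universe = members)
    expect_equal(sf$fscore[i], cm$fscore)
  }
  # skipped sets are exactly those with no reference edges inside
  for (nm in attr(sf, "skipped")) {
    members <- sets$sets[[nm]]
    expect_equal(nrow(grngpea:::induced_subnetwork(ref, members)$edges), 0L)
  }
})

test_that("an exact reference yields per-set F = 1 for planted sets", {
  truth <- make_planted_grn(60, seed = 9)
  net <- truth_network(truth)
  ref <- corrupt_reference(truth, rewire_rate = 0, seed = 1)
  gs <- plant_gene_sets(truth, k_true = 4, k_null = 0,
                        size_range = c(6, 8), seed = 2)
  sf <- subnetwork_fscores(net, ref, gs$genesets_true)
  expect_true(all(sf$fscore == 1))
})

test_that("label-randomized baseline: identity hook, determinism, signal drop", {
  truth <- make_planted_grn(80, seed = 12)
  net <- truth_network(truth)
  ref <- corrupt_reference(truth, rewire_rate = 0.3, seed = 3)
  gs <- plant_gene_sets(truth, k_true = 5, k_null = 0,
                        size_range = c(7, 10), seed = 4)
  sets <- gs$genesets_true

  ident <- randomized_label_baseline(net, ref, sets, reps = 2, seed = 1,
                                     perm_fn = identity)
  direct <- subnetwork_fscores(net, ref, sets)
  expect_equal(ident$per_rep[[1]]$fscore, direct$fscore)

  b1 <- randomized_label_baseline(net, ref, sets, reps = 5, seed = 8)
  b2 <- randomized_label_baseline(net, ref, sets, reps = 5, seed = 8)
  expect_identical(b1$pooled, b2$pooled)

  # randomized labels destroy agreement: baseline mean far below true mean
  expect_gt(mean(direct$fscore), b1$mean_f)
  expect_error(randomized_label_baseline(net, ref, sets, reps = 0), "reps")
})
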