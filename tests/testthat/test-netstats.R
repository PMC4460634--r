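test_that("degree centrality and hubs follow graph structure", {
  star <- toy_network(list(c("hub", "a"), c("hub", "b"), c("hub", "c"),
                           c("hub", "d"), c("hub", "e")),
                      nodes = c("hub", letters[1:5], "lonely"))
  d <- degree_centrality(star)
  expect_equal(unname(d["hub"]), 5L)
  expect_equal(unname(d["lonely"]), 0L)
  expect_equal(hub_table(star, top = 1)$gene_id, "hub")

  rnd <- random_network(p = 40, n_edges = 150, seed = 7)
  expect_equal(sum(degree_centrality(rnd)), 2L * nrow(rnd$edges))
  # deterministic tie order: degree desc, id asc
  ht <- hub_table(rnd, top = 40)
  expect_true(all(diff(ht$degree) <= 0))
})

test_that("edge density matches its closed form", {
  k4 <- toy_network(combn(letters[1:4], 2, simplify = FALSE))
  expect_equal(edge_density(k4), 1)
  net <- toy_network(list(c("a", "b"), c("c", "d"), c("e", "f")),
                     nodes = letters[1:6])
  expect_equal(edge_density(net), 3 / 15)
  empty <- grn_network(letters[1:5])
  expect_equal(edge_density(empty), 0)
})

test_that("power-law exponent estimate recovers a known exponent", {
  set.seed(14)
  support <- 10:2000
  degs <- sample(support, 10000, replace = TRUE, prob = support^(-4))
  est <- powerlaw_exponent(degs, xmin = 10)
  expect_lt(abs(est - 4.0), 0.15)
  # scale form: doubling degrees with doubled xmin moves the estimate little
  est2 <- powerlaw_exponent(2L * degs, xmin = 20)
  expect_lt(abs(est2 - est), 0.3)
  expect_error(powerlaw_exponent(degs[1:20]), "50")
  expect_error(powerlaw_exponent(rep(3L, 100)), "equal")
})

test_that("average shortest path is exact on small graphs", {
  path3 <- toy_network(list(c("a", "b"), c("b", "c")))
  expect_equal(avg_shortest_path(path3), 4 / 3)
  k5 <- toy_network(combn(letters[1:5], 2, simplify = FALSE))
  expect_equal(avg_shortest_path(k5), 1)
  expect_error(avg_shortest_path(grn_network(character())), "empty")
})

test_that("sampled path estimate agrees with the exact mean", {
  g <- make_planted_grn(800, seed = 17)
  net <- giant_component(truth_network(g))
  exact <- avg_shortest_path(net, max_exact = 2000)
  sampled <- avg_shortest_path(net, max_exact = 100, n_pairs = 20000, seed = 4)
  # distances on these graphs have sd ~1; 3 SE of a 20k-pair sample
  expect_lt(abs(sampled - exact), 3 * 1.5 / sqrt(20000) * 3)
})

test_that("giant component selection and partition law", {
  two_tri <- toy_network(list(c("a", "b"), c("b", "c"), c("a", "c"),
                              c("x", "y"), c("y", "z"), c("x", "z"),
                              c("p", "q")))
  gcc <- giant_component(two_tri)
  expect_equal(length(gcc$nodes), 3L)
  expect_equal(gcc$nodes, c("a", "b", "c"))  # tie broken by smallest member
  conn <- toy_network(list(c("a", "b"), c("b", "c")))
  expect_equal(giant_component(conn)$nodes, conn$nodes)
  comp_sizes <- igraph::components(as_igraph(two_tri))$csize
  expect_equal(sum(comp_sizes), length(two_tri$nodes))
})

test_that("network summary fields are internally consistent", {
  net <- random_network(p = 60, n_edges = 200, seed = 9)
  s <- network_summary(net)
  expect_equal(s$n_edges, nrow(net$edges))
  expect_equal(s$density, edge_density(net))
  expect_equal(sum(s$degree), 2 * s$n_edges)
  expect_lte(s$gcc_size, s$n_nodes)
})

test_that("degree-rank correlation equals an independent Spearman computation", {
  set.seed(77)
  for (i in 1:100) {
    a <- random_network(p = 25, n_edges = sample(20:60, 1), seed = i)
    b <- random_network(p = 25, n_edges = sample(20:60, 1), seed = i + 500)
    da <- degree_centrality(a)
    db <- degree_centrality(b)
    expect_equal(degree_rank_correlation(a, b),
                 suppressWarnings(cor(da, db, method = "spearman")))
  }
  expect_error(degree_rank_correlation(grn_network("x"), grn_network("y")),
               "shared genes")
})
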