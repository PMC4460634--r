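test_that("Pearson-estimator MI matches its closed form and caps at rho = 1", {
  set.seed(1)
  x <- rnorm(50)
  expect_equal(mi_pearson(x, x), -0.5 * log(1e-12), tolerance = 1e-6)
  expect_true(is.finite(mi_pearson(x, x)))
  expect_error(mi_pearson(x, rep(1, 50)), "constant")
  expect_error(mi_pearson(x[1:2], x[1:2]), "length")

  # I = -0.5 log(1 - rho^2) on vectors with known correlation
  y <- rnorm(50)
  r <- cor(x, y)
  expect_equal(mi_pearson(x, y), -0.5 * log(1 - r^2))
})

test_that("MI matrix equals the pairwise oracle entrywise", {
  m <- random_expression(4, 50, seed = 2)
  mm <- mi_matrix(m)
  expect_equal(mm$values, oracle_mi(m), tolerance = 1e-12)
  expect_equal(mm$values, t(mm$values))
  expect_equal(unname(diag(mm$values)), rep(0, 4))
  expect_true(all(mm$values >= 0))

  dup <- m
  dup[2, ] <- dup[1, ]
  mmd <- mi_matrix(dup)
  expect_equal(mmd$values[1, 2], -0.5 * log(1e-12), tolerance = 1e-6)

  const <- m; const[3, ] <- 5
  expect_error(mi_matrix(const), "constant")
})

test_that("null MI pool is deterministic, calibrated, and rank-consistent", {
  m <- coupled_expression(p = 6, n = 40, pairs = list(c(1, 2)), seed = 3)
  p1 <- null_mi_pool(m, n_draws = 3000, seed = 7)
  p2 <- null_mi_pool(m, n_draws = 3000, seed = 7)
  expect_identical(p1$values, p2$values)
  expect_true(all(p1$values >= 0))
  expect_length(p1$values, 3000)

  # rank statistic with the +1 correction: a value above every pool draw has
  # p = 1/(n_draws+1); the pool's own maximum (inclusive tail) has 2/(n+1)
  expect_equal(grngpea:::empirical_pvalue(max(p1$values) + 1, p1$values),
               1 / 3001)
  expect_equal(grngpea:::empirical_pvalue(max(p1$values), p1$values),
               2 / 3001)
  expect_warning(null_mi_pool(m, n_draws = 500, seed = 1), "1000")

  # permutation destroys dependence: pool of strongly coupled data matches
  # the analytic null of independent Gaussians, I = -0.5 log(1 - r^2) with
  # r^2 ~ Beta(1/2, (n-2)/2)
  set.seed(99)
  r2 <- rbeta(3000, 1 / 2, (40 - 2) / 2)
  analytic <- -0.5 * log(1 - pmin(r2, 1 - 1e-12))
  ks <- suppressWarnings(ks.test(p1$values, analytic))
  expect_gt(ks$p.value, 0.001)
})

test_that("C3Net equals the brute-force reference on toy data", {
  for (seed in 1:3) {
    m <- coupled_expression(p = 6, n = 50, pairs = list(c(1, 2), c(4, 5)),
                            coupling = 0.85, seed = seed)
    pool <- null_mi_pool(m, n_draws = 4000, seed = 11)
    net <- c3net(m, alpha = 0.05, pool = pool)
    expect_identical(edge_key_set(net),
                     oracle_c3net_edges(m, pool$values, alpha = 0.05))
    expect_lte(nrow(net$edges), nrow(m))  # at most one candidate per gene
  }
})

test_that("C3Net finds exactly a duplicated pair among independent noise", {
  m <- random_expression(8, 60, seed = 5)
  m[2, ] <- m[7, ] + rnorm(60, sd = 1e-6)
  pool <- null_mi_pool(m, n_draws = 4000, seed = 1)
  net <- c3net(m, alpha = 0.05, pool = pool)
  expect_true("g02|g07" %in% edge_key_set(net))
  expect_warning(net0 <- c3net(m, alpha = 1e-12, pool = pool), "empty")
  expect_equal(nrow(net0$edges), 0L)
})

test_that("BC3Net reduces to C3Net at B = 1 without resampling", {
  m <- coupled_expression(p = 6, n = 40, pairs = list(c(1, 3)), seed = 8)
  pool <- null_mi_pool(m, n_draws = 4000, seed = 2)
  b1 <- bc3net(m, B = 1, seed = 4, resample = FALSE, pool = pool,
               alpha_edge = 1)
  c1 <- c3net(m, pool = pool)
  expect_identical(edge_key_set(b1), edge_key_set(c1))
  expect_true(all(b1$edges$ecr == 1))
})

test_that("BC3Net consensus rates are multiples of 1/B and alpha is monotone", {
  m <- coupled_expression(p = 10, n = 60,
                          pairs = list(c(1, 2), c(3, 4), c(5, 6)), seed = 6)
  pool <- null_mi_pool(m, n_draws = 4000, seed = 3)
  net <- bc3net(m, B = 10, seed = 5, pool = pool)
  expect_true(all(abs(net$edges$ecr * 10 - round(net$edges$ecr * 10)) < 1e-12))
  expect_true(all(net$edges$ecr > 0 & net$edges$ecr <= 1))

  loose <- bc3net(m, B = 10, seed = 5, pool = pool, alpha_edge = 0.5)
  expect_true(all(edge_key_set(net) %in% edge_key_set(loose)))

  expect_error(bc3net(m, B = 0), "B must be")
})

test_that("relevance networks keep the expected top fraction of pairs", {
  m <- random_expression(10, 40, seed = 9)
  net <- relevance_network(m, "abscorr", percentile = 0.9)
  expect_equal(nrow(net$edges), ceiling(0.1 * choose(10, 2)))
  # selected scores exceed every unselected score
  rho <- abs(cor(t(m)))
  sel <- net$edges$ecr
  all_scores <- rho[upper.tri(rho)]
  expect_gte(min(sel), sort(all_scores, decreasing = TRUE)[length(sel)])

  clr <- relevance_network(m, "clr", percentile = 0.8)
  expect_equal(nrow(clr$edges), ceiling(0.2 * choose(10, 2)))
  expect_true(all(clr$edges$ecr > 0))  # both-z-negative pairs score 0

  expect_error(relevance_network(m, "abscorr", percentile = 1), "percentile")
  const_scores <- matrix(1, 4, 40,
                         dimnames = list(paste0("g", 1:4), paste0("s", 1:40)))
  expect_error(relevance_network(const_scores + rnorm(160) * 0, "abscorr", 0.5))
})

test_that("ensemble inference recovers the planted truth better than the
           absolute-correlation baseline at matched edge count", {
  f_bc3 <- numeric(10); f_abs <- numeric(10)
  for (r in 1:10) {
    truth <- make_planted_grn(100, seed = 600 + r)
    m <- simulate_expression(truth, n = 200, seed = 600 + r)
    net <- bc3net(m, B = 20, seed = 600 + r, n_draws = 10000)
    pct <- 1 - max(1, nrow(net$edges)) / choose(nrow(m), 2)
    base <- relevance_network(m, "abscorr", percentile = pct)
    tn <- truth_network(truth)
    f_bc3[r] <- confusion_vs_reference(net, tn, universe = tn$nodes)$fscore
    f_abs[r] <- confusion_vs_reference(base, tn, universe = tn$nodes)$fscore
  }
  expect_gt(median(f_bc3), median(f_abs))
})
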