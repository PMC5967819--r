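test_that("harden takes the max-membership cluster with low-index ties", {
  U <- rbind(c(1, 0.2, 0.5, 1 / 3),
             c(0, 0.8, 0.5, 1 / 3),
             c(0, 0.0, 0.0, 1 / 3))
  expect_equal(harden(U), c(1L, 2L, 1L, 1L))
  withr::local_seed(61)
  U <- matrix(runif(60), 4, 15)
  expect_equal(harden(U), apply(U, 2, which.max))
})

test_that("f_measure matches hand arithmetic and the loop oracle", {
  # perfect diagonal table
  expect_equal(f_measure(diag(c(4, 6, 2))), 1)
  # n_ij = 5 of class with n_i = 10 in a pure cluster of n_j = 5:
  # recall 0.5, precision 1, F = 2/3; the other 5 land in a pure cluster
  tab <- rbind(c(5, 5), c(0, 0))
  expect_equal(f_measure(tab), 2 / 3 * 1)  # single non-empty class
  withr::local_seed(62)
  for (rep in 1:15) {
    tab <- matrix(rpois(12, 4), 3, 4)
    if (sum(tab) == 0) next
    expect_equal(f_measure(tab), f_measure_oracle(tab))
    expect_gte(f_measure(tab), 0)
    expect_lte(f_measure(tab), 1)
  }
})

test_that("f_measure is 1 exactly on relabelled class partitions", {
  withr::local_seed(63)
  truth <- sample(letters[1:3], 40, replace = TRUE)
  relabel <- c(a = 2L, b = 3L, c = 1L)
  expect_equal(f_measure(truth, relabel[truth]), 1)
  expect_lt(f_measure(truth, sample(relabel[truth])), 1)
})

test_that("entropy matches closed forms and the loop oracle in both bases", {
  expect_equal(cluster_entropy(diag(c(3, 7))), 0)  # pure clusters
  # one cluster, two equal classes -> ln 2 (or log10 2)
  tab <- matrix(c(5, 5), ncol = 1)
  expect_equal(cluster_entropy(tab), log(2))
  expect_equal(cluster_entropy(tab, base = 10), log10(2))
  withr::local_seed(64)
  for (rep in 1:10) {
    tab <- matrix(rpois(12, 3), 3, 4)
    if (any(colSums(tab) == 0)) next
    expect_equal(cluster_entropy(tab), entropy_oracle(tab))
    expect_equal(cluster_entropy(tab, base = 10), entropy_oracle(tab, 10))
    expect_lte(cluster_entropy(tab), log(nrow(tab)) + 1e-12)
  }
})

test_that("hypergeometric p-value matches the enumeration oracle", {
  expect_equal(cluster_pvalue(10, 5, 4, 3), 55 / 210)
  expect_equal(cluster_pvalue(10, 10, 4, 4), 1)  # every object annotated
  expect_equal(cluster_pvalue(8, 3, 5, 0), 1)    # >= 0 successes is certain
  withr::local_seed(65)
  for (rep in 1:40) {
    N <- sample(4:12, 1)
    M <- sample(1:N, 1)
    n <- sample(1:N, 1)
    m <- sample(0:min(n, M), 1)
    expect_equal(cluster_pvalue(N, M, n, m), pvalue_oracle(N, M, n, m),
                 tolerance = 1e-12)
  }
  expect_error(cluster_pvalue(10, 11, 4, 2), "<=")
  expect_error(cluster_pvalue(10, 5, 4, 5), "<=")
})

test_that("p-value is non-increasing in the observed count m", {
  for (m in 1:6) {
    expect_lte(cluster_pvalue(20, 8, 6, m), cluster_pvalue(20, 8, 6, m - 1))
  }
})

test_that("clustering score collapses to the cutoff when nothing is significant", {
  # one class only: every cluster has enrichment p-value 1
  truth <- rep("a", 12)
  cl <- rep(1:3, each = 4)
  cs <- clustering_score(truth, cl)
  expect_equal(cs$ns, 0)
  expect_equal(cs$nl, 3)
  expect_equal(cs$cs, 0.05)
})

test_that("clustering score averages significant min p-values", {
  # perfectly enriched two-cluster case, checked step by step with the
  # enumeration oracle
  truth <- rep(c("a", "b"), each = 6)
  cl <- rep(1:2, each = 6)
  p_each <- pvalue_oracle(12, 6, 6, 6)
  cs <- clustering_score(truth, cl)
  expect_equal(cs$ns, 2)
  expect_equal(cs$cs, p_each)
  expect_equal(cs$neg_log10_cs, -log10(p_each))
  expect_equal(cs$clusters$min_p, rep(p_each, 2))
  expect_true(all(cs$clusters$significant))
})

test_that("clustering score improves as clusters become more class-enriched", {
  truth <- rep(c("a", "b"), each = 10)
  swaps <- list(c(), c(1, 11), c(1, 2, 11, 12), c(1:3, 11:13))
  cs_vals <- vapply(swaps, function(sw) {
    cl <- rep(1:2, each = 10)
    cl[sw] <- 3 - cl[sw]  # cross-assign some objects
    clustering_score(truth, cl)$cs
  }, numeric(1))
  expect_true(all(diff(cs_vals) >= 0))  # less mixing -> lower (better) CS
})

test_that("evaluate_clustering returns one tidy row consistent with its parts", {
  d <- simulate_warped_series(k = 2, n_per_cluster = 8, seed = 66)
  fit <- fcmdd(d, k = 2)
  row <- evaluate_clustering(fit, d$label)
  expect_equal(nrow(row), 1)
  expect_equal(row$f_measure, f_measure(d$label, fit$cluster))
  expect_equal(row$entropy, cluster_entropy(d$label, fit$cluster))
  expect_equal(row$cs, clustering_score(d$label, fit$cluster)$cs)
  # labels stored in the fit are the default truth
  expect_equal(evaluate_clustering(fit), row)
})

test_that("contingency table invariants hold", {
  withr::local_seed(67)
  truth <- sample(c("x", "y", "z"), 30, replace = TRUE)
  cl <- sample(1:4, 30, replace = TRUE)
  tab <- cluster_contingency(truth, cl)
  expect_equal(sum(tab), 30)
  expect_equal(rowSums(tab), c(table(truth))[rownames(tab)])
  expect_equal(colSums(tab), c(table(cl))[colnames(tab)])
  expect_error(cluster_contingency(truth, cl[-1]), "same objects")
})
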