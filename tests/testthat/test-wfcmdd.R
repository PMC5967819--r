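test_that("objective matches a triple-loop oracle and trivial cases", {
  withr::local_seed(31)
  for (rep in 1:10) {
    n <- sample(5:12, 1); C <- sample(2:3, 1)
    D <- random_distmat(n)
    med <- sample(n, C)
    U <- update_memberships(D, med, fuzzifier = 2.3)
    w <- runif(n, 0.5, 3)
    expect_equal(wfcmdd_objective(D, U, w, med, 2.3),
                 objective_oracle(D, U, w, med, 2.3))
    expect_gte(wfcmdd_objective(D, U, w, med, 2.3), 0)
  }

  # all objects on their medoid -> J = 0
  D0 <- matrix(0, 4, 4)
  U <- matrix(0.5, 2, 4)
  expect_equal(wfcmdd_objective(D0, U, rep(1, 4), c(1, 2), 2), 0)

  # C = 1 collapses to a weighted distance sum
  D <- random_distmat(6)
  U1 <- matrix(1, 1, 6)
  w <- runif(6)
  expect_equal(wfcmdd_objective(D, U1, w, 3L, 2), sum(w * D[, 3]))
})

test_that("membership update normalises columns and honours Eq-style ratios", {
  # equidistant object -> uniform memberships
  D <- matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3)
  U <- update_memberships(D, c(1, 2, 3), fuzzifier = 2)
  expect_equal(U[, 1], c(1, 0, 0))            # object 1 is medoid 1
  expect_equal(colSums(U), rep(1, 3))

  # hand-computed two-cluster case: distances (1, 3), m = 2 -> (0.75, 0.25)
  D2 <- matrix(0, 3, 3)
  D2[3, 1] <- D2[1, 3] <- 1
  D2[3, 2] <- D2[2, 3] <- 3
  D2[1, 2] <- D2[2, 1] <- 4
  U2 <- update_memberships(D2, c(1, 2), fuzzifier = 2)
  expect_equal(U2[, 3], c(0.75, 0.25))
})

test_that("zero-distance singularities split membership among tied medoids", {
  D <- matrix(c(0, 0, 1,
                0, 0, 1,
                1, 1, 0), 3)
  U <- update_memberships(D, c(1, 2), fuzzifier = 2.3)
  expect_equal(U[, 1], c(0.5, 0.5))  # object 1 at distance 0 from both medoids
  expect_equal(colSums(U), rep(1, 3))
})

test_that("column normalisation holds across random instances with zeros", {
  withr::local_seed(32)
  for (rep in 1:25) {
    n <- sample(4:15, 1); C <- sample(2:min(4, n), 1)
    D <- random_distmat(n, zero_pairs = sample(0:2, 1))
    U <- update_memberships(D, sample(n, C), fuzzifier = runif(1, 1.3, 3))
    expect_true(all(U >= 0 & U <= 1))
    expect_equal(colSums(U), rep(1, n), tolerance = 1e-12)
  }
})

test_that("deterministic initialisation follows the centre-then-farthest rule", {
  # three collinear series: B is central
  d <- ts_dataset(list(c(0, 0, 0), c(5, 5, 5), c(10, 10, 10)))
  D <- ts_distances(d)
  expect_equal(initialize_medoids(D, 1), 2L)
  # second medoid: farthest from the first
  expect_equal(initialize_medoids(D, 2), c(2L, 1L))  # ties break low: 1 and 3 equidistant

  withr::local_seed(33)
  for (rep in 1:10) {
    D <- random_distmat(8)
    med <- initialize_medoids(D, 3)
    expect_equal(med[1], which.min(rowSums(D)))
    cand2 <- which.max(replace(D[, med[1]], med[1], -Inf))
    expect_equal(med[2], cand2)
    far3 <- rowSums(D[, med[1:2]])
    far3[med[1:2]] <- -Inf
    expect_equal(med[3], which.max(far3))
    expect_false(anyDuplicated(med) > 0)
  }
  expect_error(initialize_medoids(random_distmat(3), 4), "1..3")
})

test_that("medoid selection equals brute force over the candidate set", {
  withr::local_seed(34)
  for (rep in 1:15) {
    n <- sample(6:14, 1); C <- 3; q <- 3
    D <- random_distmat(n)
    med <- initialize_medoids(D, C)
    U <- update_memberships(D, med, 2.3)
    w <- runif(n, 0.5, 2)
    sel <- select_medoids(D, U, w, 2.3, q = q, current = med)
    expect_false(anyDuplicated(sel) > 0)
    taken <- integer(0)
    for (c in 1:C) {
      cand <- union(order(-U[c, ], seq_len(n))[1:q], med[c])
      cand <- setdiff(cand, taken)
      costs <- vapply(cand, function(x) sum(w * U[c, ]^2.3 * D[, x]),
                      numeric(1))
      expect_equal(sel[c], cand[order(costs, cand)][1])
      taken <- c(taken, sel[c])
    }
  }
})

test_that("q = N medoid selection is the exhaustive argmin", {
  withr::local_seed(35)
  n <- 10
  D <- random_distmat(n)
  med <- initialize_medoids(D, 2)
  U <- update_memberships(D, med, 2)
  w <- rep(1, n)
  sel <- select_medoids(D, U, w, 2, q = n, current = med)
  all_costs1 <- vapply(1:n, function(x) sum(w * U[1, ]^2 * D[, x]), numeric(1))
  expect_equal(sel[1], which.min(all_costs1))
})

test_that("an object at distance zero from all members is selected at cost zero", {
  D <- matrix(1, 5, 5); diag(D) <- 0
  D[, 4] <- 0; D[4, ] <- 0
  U <- matrix(c(rep(1, 5), rep(0, 5)), nrow = 2, byrow = TRUE)
  sel <- select_medoids(D, U, rep(1, 5), 2, q = 5, current = c(1L, 2L))
  expect_equal(sel[1], 4L)
})

test_that("fit is deterministic, converges, and separates well-separated groups", {
  d <- simulate_warped_series(k = 3, n_per_cluster = 8, noise_sd = 0.02,
                              seed = 41)
  fit1 <- fcmdd(d, k = 3)
  fit2 <- fcmdd(d, k = 3)
  expect_identical(fit1$membership, fit2$membership)
  expect_identical(fit1$medoids, fit2$medoids)
  expect_true(fit1$converged)
  expect_equal(f_measure(d$label, fit1$cluster), 1)
  # crisp memberships on the hardened assignment
  top <- fit1$membership[cbind(fit1$cluster, seq_len(ncol(fit1$membership)))]
  expect_true(all(top > 0.5))
})

test_that("objective trace is non-increasing and bounded below by zero", {
  withr::local_seed(42)
  for (rep in 1:10) {
    d <- random_tiny_dataset(sample(8:16, 1), max_len = 8)
    fit <- fcmdd(d, k = sample(2:3, 1), fuzzifier = runif(1, 1.5, 3))
    expect_true(all(diff(fit$objective_trace) <= 1e-9))
    expect_true(all(fit$objective_trace >= 0))
  }
})

test_that("fit with a generous cap always reaches a stable medoid set", {
  withr::local_seed(43)
  for (rep in 1:10) {
    D <- random_distmat(sample(8:20, 1))
    fit <- fcmdd(D, k = 3, max_iter = 1000)
    expect_true(fit$converged)
    expect_lt(fit$iterations, 1000)
  }
})

test_that("euclidean metric runs the same loop (weighted FCMdd)", {
  withr::local_seed(44)
  d <- ts_dataset(lapply(1:12, function(i) rnorm(10)))
  fit <- fcmdd(d, k = 2, metric = "euclidean")
  expect_equal(fit$config$metric, "euclidean")
  Dm <- ts_distances(d, metric = "euclidean")
  ref <- fcmdd(Dm, k = 2)
  expect_equal(fit$medoids, ref$medoids)
  expect_equal(fit$membership, ref$membership)
})

test_that("broom methods return tidy shapes", {
  d <- simulate_warped_series(k = 2, n_per_cluster = 6, seed = 8)
  fit <- fcmdd(d, k = 2)
  g <- glance(fit)
  expect_equal(nrow(g), 1)
  expect_named(g, c("k", "n", "objective", "iterations", "converged",
                    "metric", "algorithm"))
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_equal(sum(td$size), 12)
  expect_equal(sum(td$total_membership), 12, tolerance = 1e-9)
  au <- augment(fit, d)
  expect_equal(nrow(au), 12)
  expect_true(all(c(".cluster", ".membership") %in% names(au)))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_medoids(fit), "ggplot")
})
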