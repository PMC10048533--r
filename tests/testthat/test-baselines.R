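test_that("k-means solves the canonical 1-D toy exactly", {
  X <- matrix(c(0, 0, 1, 10, 10, 11), 6, 1)
  fit <- baseline_fit(X, baseline_config(K = 2, variant = "kmeans",
                                         restarts = 10, seed = 1))
  expect_equal(sort(fit$model$centers[, 1]), c(1 / 3, 31 / 3), tolerance = 1e-12)
  expect_equal(fit$best_objective, 2 / 3 + 2 / 3, tolerance = 1e-12)
  # and it matches the exhaustive 2-partition optimum
  expect_equal(fit$best_objective, oracle_kmeans2_1d(X[, 1]), tolerance = 1e-12)
})

test_that("k-means degenerate and symmetry cases", {
  set.seed(8)
  X <- matrix(rnorm(10), 5, 2)
  # K = N: every point its own center, objective 0
  fit <- baseline_fit(X, baseline_config(K = 5, variant = "kmeans",
                                         restarts = 5, seed = 2))
  expect_equal(fit$best_objective, 0, tolerance = 1e-12)
  # duplicated rows always share an assignment
  Xd <- rbind(X, X[2, ])
  fit <- baseline_fit(Xd, baseline_config(K = 2, variant = "kmeans",
                                          restarts = 5, seed = 3))
  expect_equal(fit$hard_labels[6], fit$hard_labels[2])
})

test_that("k-means agrees with stats::kmeans on well-separated data", {
  d <- make_blobs(blob_spec(c(30, 30, 30), m_informative = 2, separation = 10,
                            seed = 4))
  fit <- baseline_fit(d, baseline_config(K = 3, variant = "kmeans",
                                         restarts = 10, seed = 1))
  ref <- stats::kmeans(d$values, centers = 3, nstart = 10)
  expect_equal(fit$best_objective, ref$tot.withinss, tolerance = 1e-8)
  expect_equal(clustering_accuracy(fit$hard_labels, ref$cluster), 1)
})

test_that("wk-means weights follow the dispersion structure", {
  set.seed(9)
  base <- rnorm(40)
  # all features identical copies: symmetric weights 1/M
  X <- cbind(base, base, base)
  fit <- baseline_fit(X, baseline_config(K = 2, variant = "wkmeans",
                                         restarts = 5, seed = 1))
  expect_equal(fit$model$global_weights, rep(1 / 3, 3), tolerance = 1e-9)
  expect_equal(sum(fit$model$global_weights), 1, tolerance = 1e-12)
  # a pure-noise feature with much larger within-cluster dispersion gets
  # the smallest weight (beta = 2)
  d <- make_blobs(blob_spec(c(25, 25), m_informative = 2, separation = 8,
                            seed = 5))
  Xn <- cbind(d$values, rnorm(50, sd = 12))
  fit <- baseline_fit(Xn, baseline_config(K = 2, variant = "wkmeans",
                                          restarts = 10, seed = 2))
  expect_equal(which.min(fit$model$global_weights), 3L)
  # M = 1 reduces to plain k-means assignments
  X1 <- matrix(c(0, 0.2, 0.1, 5, 5.2, 5.1), 6, 1)
  fw <- baseline_fit(X1, baseline_config(K = 2, variant = "wkmeans",
                                         restarts = 5, seed = 3))
  fk <- baseline_fit(X1, baseline_config(K = 2, variant = "kmeans",
                                         restarts = 5, seed = 3))
  expect_equal(clustering_accuracy(fw$hard_labels, fk$hard_labels), 1)
})

test_that("fcm memberships follow the inverse-distance-ratio form", {
  # point equidistant from all centers: uniform membership
  U <- fwec:::.fcm_memberships(matrix(c(2, 2, 2), 1, 3), expo = 2)
  expect_equal(U, matrix(1 / 3, 1, 3))
  # coincident point: hard singleton membership
  U <- fwec:::.fcm_memberships(matrix(c(0, 3), 1, 2), expo = 2)
  expect_equal(U, matrix(c(1, 0), 1, 2))
  # m -> infinity (exponent -> 0): uniform memberships on fixed centers
  U <- fwec:::.fcm_memberships(matrix(runif(8, 1, 2), 2, 4), expo = 1e-12)
  expect_equal(U, matrix(1 / 4, 2, 4), tolerance = 1e-9)
})

test_that("fcm converges to symmetric centers on symmetric 1-D clusters", {
  a <- 3
  X <- matrix(c(-a - 0.1, -a, -a + 0.1, a - 0.1, a, a + 0.1), 6, 1)
  fit <- baseline_fit(X, baseline_config(K = 2, variant = "fcm", m = 2,
                                         restarts = 5, seed = 1))
  ctrs <- sort(fit$model$centers[, 1])
  expect_equal(ctrs[1], -ctrs[2], tolerance = 1e-6)
  expect_equal(rowSums(fit$model$fuzzy_U), rep(1, 6), tolerance = 1e-12)
})

test_that("baseline objective traces are non-increasing", {
  d <- make_blobs(blob_spec(c(20, 20, 20), m_informative = 3, separation = 4,
                            seed = 6))
  for (v in c("kmeans", "wkmeans", "fcm")) {
    fit <- baseline_fit(d, baseline_config(K = 3, variant = v, restarts = 5,
                                           seed = 2))
    tr <- fit$model$objective_trace
    if (length(tr) > 1) expect_lte(max(diff(tr)), 1e-10)
  }
})

test_that("fcm with m near 1 approaches k-means on separated blobs", {
  d <- make_blobs(blob_spec(c(40, 40), m_informative = 2, separation = 8,
                            seed = 7))
  ff <- baseline_fit(d, baseline_config(K = 2, variant = "fcm", m = 1.01,
                                        restarts = 5, seed = 1))
  fk <- baseline_fit(d, baseline_config(K = 2, variant = "kmeans",
                                        restarts = 5, seed = 1))
  expect_gte(clustering_accuracy(ff$hard_labels, fk$hard_labels), 0.99)
})

test_that("baseline config domains are enforced", {
  expect_error(baseline_config(K = 2, variant = "wkmeans", beta = 1), "beta")
  expect_error(baseline_config(K = 2, variant = "fcm", m = 1), "m > 1")
  expect_silent(baseline_config(K = 2, variant = "wkmeans", beta = -1))
})
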