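test_that("correlation distance matches hand-computed values", {
  x <- c(1, 2, 3)
  expect_equal(corr_distance(x, x), 0)
  expect_equal(corr_distance(x, -x), 2)
  expect_equal(corr_distance(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(corr_distance(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
})

test_that("standardization identity holds: ||x - y||^2 / 2 == 1 - r", {
  set.seed(61)
  for (i in 1:50) {
    p <- sample(3:40, 1)
    x <- rnorm(p)
    y <- rnorm(p)
    xs <- std_vec(x)
    ys <- std_vec(y)
    expect_equal(sum((xs - ys)^2) / 2, 1 - cor(x, y), tolerance = 1e-10)
  }
})

test_that("feature matrix pools volumes and the index round-trips", {
  set.seed(5)
  series <- list(a = matrix(rnorm(10 * 100), 10), b = matrix(rnorm(10 * 125), 10))
  fm <- build_feature_matrix(series)
  expect_equal(ncol(fm$features), 225L)
  expect_equal(nrow(fm$index), 225L)
  # column -> (participant, time) -> column is the identity
  for (col in c(1L, 100L, 101L, 225L)) {
    row <- fm$index[fm$index$column == col, ]
    expect_identical(fm$features[, col],
                     series[[row$participant]][, row$time])
  }
  one <- build_feature_matrix(series["a"])
  expect_identical(one$features, series$a)
  expect_error(build_feature_matrix(list(series$a, matrix(0, 9, 5))),
               "same parcellation")
})

test_that("k-means attains the enumerated optimum on small instances", {
  set.seed(71)
  for (rep in 1:100) {
    n <- sample(4:8, 1)
    p <- sample(4:8, 1)
    x <- matrix(rnorm(n * p), p, n)
    best <- enumerate_best_inertia_2(x)
    fit <- kmeans_corr(x, k = 2, n_restarts = 100, seed = rep)
    expect_lte(fit$inertia, best + 1e-8)
    expect_gte(fit$inertia, best - 1e-8)
  }
})

test_that("k-means recovers planted orthogonal patterns", {
  set.seed(83)
  p <- 40
  c1 <- std_vec(rnorm(p))
  c2 <- std_vec(residuals(lm(rnorm(p) ~ 0 + c1)))  # orthogonal to c1
  truth <- sample(1:2, 300, replace = TRUE)
  x <- sapply(truth, function(s) (if (s == 1) c1 else c2) + rnorm(p, 0, 0.15))
  fit <- kmeans_corr(x, k = 2, n_restarts = 10, seed = 1)
  expect_gt(label_agreement(truth, fit$assignments, 2), 0.95)
})

test_that("k-means edge cases: k = n, k > n, determinism", {
  set.seed(89)
  x <- matrix(rnorm(6 * 10), 10, 6)
  fit <- kmeans_corr(x, k = 6, n_restarts = 5, seed = 2)
  expect_lt(fit$inertia, 1e-10)
  expect_equal(sort(unique(fit$assignments)), 1:6)
  expect_error(kmeans_corr(x, k = 7), "exceeds")
  f1 <- kmeans_corr(x, k = 3, seed = 42)
  f2 <- kmeans_corr(x, k = 3, seed = 42)
  expect_identical(f1$assignments, f2$assignments)
  expect_identical(f1$inertia, f2$inertia)
})

test_that("fractional occupancy counts volumes per participant", {
  idx <- data.frame(participant = rep("a", 5), time = 1:5, column = 1:5)
  fo <- fractional_occupancy(c(1L, 1L, 2L, 3L, 1L), idx, k = 3)
  expect_equal(unname(fo["a", ]), c(0.6, 0.2, 0.2))

  idx2 <- data.frame(participant = rep(c("a", "b"), c(4, 3)), time = c(1:4, 1:3),
                     column = 1:7)
  fo2 <- fractional_occupancy(rep(2L, 7), idx2, k = 4)
  expect_equal(unname(fo2[, 2]), c(1, 1))
  expect_true(all(fo2[, -2] == 0))
  expect_true(all(abs(rowSums(fo2) - 1) < 1e-12))
  expect_error(fractional_occupancy(1:3, idx2, k = 4), "per pooled volume")
})

test_that("high-occupancy selection ranks by mean FO with index tie-breaks", {
  fo <- rbind(c(0.30, 0.20, 0.18, 0.17, 0.15),
              c(0.20, 0.28, 0.18, 0.17, 0.17))
  colnames(fo) <- paste0("fo_", 1:5)
  sel <- select_high_occupancy(fo)
  expect_equal(sel$top, c(1L, 2L))
  expect_equal(unname(sel$fo_high[1]), 0.25)

  # exact tie between ranks 2 and 3 -> lower state index selected
  fo_tie <- rbind(c(0.30, 0.20, 0.20, 0.15, 0.15))
  sel_tie <- select_high_occupancy(fo_tie)
  expect_equal(sel_tie$top, c(1L, 2L))

  sel_sum <- select_high_occupancy(fo, method = "sum")
  expect_equal(unname(sel_sum$fo_high[1]), 0.50)
})

test_that("clustering the synthetic cohort recovers planted states", {
  cfg <- tiny_bold_config()
  co <- simulate_cohort(cfg, include_bold = TRUE)
  model <- estimate_brain_states(co$bold, k = 5, n_restarts = 10, seed = 11)
  truth <- unlist(co$sequences)
  expect_gt(label_agreement(truth, model$assignments, 5), 0.90)

  fo <- fractional_occupancy(model)
  expect_true(all(abs(rowSums(fo) - 1) < 1e-12))
  sel <- select_high_occupancy(fo)
  # the two selected states are the planted DMN states (up to label permutation)
  tab <- table(factor(truth, levels = 1:5), model$assignments)
  perm <- apply(tab, 1, which.max)
  expect_setequal(sel$top, perm[1:2])
})

test_that("permuting participants leaves inertia and occupancies invariant", {
  cfg <- tiny_bold_config(seed = 13, n = 12)
  co <- simulate_cohort(cfg, include_bold = TRUE)
  m1 <- estimate_brain_states(co$bold, k = 5, n_restarts = 8, seed = 3)
  m2 <- estimate_brain_states(rev(co$bold), k = 5, n_restarts = 8, seed = 3)
  expect_equal(m1$inertia, m2$inertia, tolerance = 1e-8)
  fo1 <- fractional_occupancy(m1)
  fo2 <- fractional_occupancy(m2)
  # match state labels across the two runs via centroid correlation
  perm <- apply(abs(cor(t(m1$centroids), t(m2$centroids))), 1, which.max)
  expect_equal(unname(fo1[rownames(fo2), ]), unname(fo2[, perm]),
               tolerance = 1e-8)
})

test_that("network profiles flag the default-mode states", {
  labels <- default_network_labels(70)
  cent <- matrix(0, 2, 70)
  cent[1, labels == "Default"] <- 1
  cent[2, ] <- -cent[1, ]
  np <- network_profile(cent, labels)
  dmn1 <- np[np$state == 1 & np$network == "Default", ]
  expect_equal(dmn1$sim_pos, 1)
  expect_equal(dmn1$sim_neg, 0)
  # negation swaps the positive and negative similarity profiles
  expect_equal(np$sim_pos[np$state == 1], np$sim_neg[np$state == 2])
  expect_equal(np$sim_neg[np$state == 1], np$sim_pos[np$state == 2])
  expect_true(all(np$sim_pos >= 0 & np$sim_pos <= 1))

  # planted DMN- state from the generator: strongest negative similarity on
  # the default network
  cfg <- tiny_bold_config(seed = 29, n = 15)
  co <- simulate_cohort(cfg, include_bold = TRUE)
  model <- estimate_brain_states(co$bold, k = 5, n_restarts = 8, seed = 7)
  truth <- unlist(co$sequences)
  perm <- apply(table(factor(truth, levels = 1:5), model$assignments), 1,
                which.max)
  npm <- network_profile(model, cfg$network_labels)
  dmn_minus <- npm[npm$state == perm[2], ]
  expect_equal(dmn_minus$network[which.max(dmn_minus$sim_neg)], "Default")
})

test_that("zero-variance volumes are rejected at input validation", {
  x <- matrix(rnorm(40), 10, 4)
  x[, 2] <- 3
  expect_error(kmeans_corr(x, k = 2), "zero-variance")
})
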