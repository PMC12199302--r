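logistic_std <- function(fit, x) {
  xs <- sweep(sweep(x[, fit$features, drop = FALSE], 2, fit$scale_mean), 2,
              fit$scale_sd, "/")
  1 / (1 + exp(-(fit$intercept + xs %*% fit$weights)))
}

logistic_data <- function(n, w, b, seed = 1, noise = 0) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * length(w)), n,
              dimnames = list(NULL, paste0("f", seq_along(w))))
  p <- 1 / (1 + exp(-(x %*% w + b)))
  if (noise > 0) p <- pmin(pmax(p + stats::rnorm(n, sd = noise), 0), 1)
  list(x = x, p = as.numeric(p))
}

test_that("logistic least squares recovers a noiseless ground truth", {
  d <- logistic_data(300, c(1.5, -0.8), 0.3)
  fit <- logistic_lsq_fit(d$x, d$p)
  expect_equal(unname(fit$weights), c(1.5, -0.8), tolerance = 1e-4)
  expect_equal(fit$intercept, 0.3, tolerance = 1e-4)
  # single feature equal to logit(p): weight 1, intercept 0
  d2 <- logistic_data(200, 1, 0, seed = 2)
  fit2 <- logistic_lsq_fit(d2$x, d2$p)
  expect_equal(unname(fit2$weights), 1, tolerance = 1e-5)
  expect_equal(fit2$intercept, 0, tolerance = 1e-5)
})

test_that("uninformative committors give a null fit", {
  set.seed(3)
  x <- matrix(stats::rnorm(200), 100, 2,
              dimnames = list(NULL, c("f1", "f2")))
  fit <- logistic_lsq_fit(x, rep(0.5, 100))
  expect_equal(unname(fit$weights), c(0, 0), tolerance = 1e-6)
  expect_equal(fit$intercept, 0, tolerance = 1e-6)
})

test_that("adjusted R-squared follows its definition", {
  expect_equal(adjusted_r2(1:10, 1:10, 3), 1)
  obs <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  pred <- obs + c(0.5, -0.5, 0.4, -0.4, 0.3, -0.3, 0.2, -0.2, 0.1, -0.1)
  r2 <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  expect_equal(adjusted_r2(obs, pred, 2), 1 - (1 - r2) * 9 / 7)
  # formula arithmetic from a stated R^2
  expect_equal(1 - (1 - 0.9) * 9 / 7, 0.8714, tolerance = 1e-4)
  # a constant-mean predictor scores zero R^2, negative adjusted
  expect_lt(adjusted_r2(obs, rep(mean(obs), 10), 2), 0)
  expect_error(adjusted_r2(1:3, 1:3, 2), "n > k")
})

test_that("committor correlation filter behaves at its boundaries", {
  set.seed(4)
  p <- stats::runif(1000)
  x <- cbind(exact = p, noise = stats::rnorm(1000))
  kept <- committor_corr_filter(x, p, threshold = 0.1)
  expect_equal(colnames(kept), "exact")
  expect_equal(ncol(committor_corr_filter(x, p, threshold = 1)), 0)
  x2 <- cbind(x, flat = rep(1, 1000))
  expect_warning(committor_corr_filter(x2, p), "constant")
})

test_that("Leiden correlation clustering recovers planted blocks", {
  set.seed(5)
  n <- 400
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n); z3 <- stats::rnorm(n)
  mk <- function(z, k) vapply(seq_len(k), function(i)
    z + stats::rnorm(n, sd = 0.05), numeric(n))
  x <- cbind(mk(z1, 3), mk(z2, 3), mk(z3, 3))
  colnames(x) <- paste0("f", 1:9)
  cl <- correlation_cluster(x, gamma = 0.6, seed = 1)
  expect_equal(length(unique(cl)), 3)
  expect_equal(length(unique(cl[1:3])), 1)
  expect_equal(length(unique(cl[4:6])), 1)
  # independent features at a large resolution become singletons
  set.seed(6)
  ind <- matrix(stats::rnorm(400 * 5), 400, 5,
                dimnames = list(NULL, paste0("g", 1:5)))
  expect_equal(length(unique(correlation_cluster(ind, gamma = 0.9))), 5)
  # a single feature is one cluster
  expect_equal(unname(correlation_cluster(ind[, 1, drop = FALSE])), 1L)
})

test_that("cluster PC1 reduction decorrelates and keeps provenance", {
  set.seed(7)
  n <- 300
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  x <- cbind(a1 = z1 + stats::rnorm(n, sd = 0.1),
             a2 = z1 + stats::rnorm(n, sd = 0.1),
             b1 = z1 + stats::rnorm(n, sd = 0.3),  # correlated with cluster a
             c1 = z2 + stats::rnorm(n, sd = 0.1),
             c2 = z2 + stats::rnorm(n, sd = 0.1),
             lone = stats::rnorm(n))
  cl <- stats::setNames(c(1L, 1L, 2L, 3L, 3L, 4L), colnames(x))
  red <- cluster_pc1_reduce(x, cl)
  # identical-signal cluster: PC1 explains essentially everything
  expect_gt(red$provenance$var_share[1], 0.95)
  cm <- abs(stats::cor(red$series))
  expect_true(all(cm[upper.tri(cm)] <= 0.7))
  # round-two merge united the a-cluster with the correlated singleton b1
  members <- lapply(red$maps, `[[`, "features")
  merged <- members[[which(vapply(members, function(m) "b1" %in% m,
                                  logical(1)))]]
  expect_true(all(c("a1", "a2") %in% merged))
  # the reduction is a reusable linear map
  expect_equal(reduce_transform(red, x), red$series)
  # singletons pass through unchanged
  expect_true(any(vapply(red$maps, function(m)
    identical(m$features, "lone") && m$weights == 1, logical(1))))
})

test_that("the MC feature search keeps planted signals and drops decoys", {
  set.seed(8)
  n <- 260
  x <- matrix(stats::rnorm(n * 8), n,
              dimnames = list(NULL, paste0("f", 1:8)))
  p <- as.numeric(1 / (1 + exp(-(1.4 * x[, 1] - 1.1 * x[, 2] + 0.8 * x[, 3]))))
  p <- pmin(pmax(p + stats::rnorm(n, sd = 0.03), 0), 1)
  ds <- committor_dataset(data.frame(id = seq_len(n), p = p), x)
  ds <- stratified_partition(ds, test_count = 20, seed = 9)
  cfg <- selection_config(n_boot = 10, mc_iterations = 60, n_repeats = 4,
                          seed = 11)
  res <- mc_feature_search(ds, cfg)
  expect_true(all(c("f1", "f2", "f3") %in% res$selected))
  expect_lte(length(setdiff(res$selected, c("f1", "f2", "f3"))), 1)
  # deterministic given the seed
  res2 <- mc_feature_search(ds, cfg)
  expect_identical(res$selected, res2$selected)
  expect_identical(res$frequency, res2$frequency)
})

test_that("bootstrap finalization recovers coefficients and scores the test set", {
  set.seed(12)
  n <- 300
  x <- matrix(stats::rnorm(n * 2), n, dimnames = list(NULL, c("f1", "f2")))
  p <- as.numeric(1 / (1 + exp(-(1.2 * x[, 1] - 0.6 * x[, 2]))))
  ds <- committor_dataset(data.frame(id = seq_len(n), p = p), x)
  ds <- stratified_partition(ds, test_count = 20, seed = 13)
  fit <- finalize_coefficients(ds, c("f1", "f2"), n_boot = 60, seed = 14)
  expect_s3_class(fit, "rc_fit")
  # scaling: recovered weights are on the z-scored scale
  expect_equal(unname(fit$weights),
               unname(c(1.2, -0.6) * fit$scale_sd), tolerance = 0.05)
  expect_lte(fit$metrics$r2, 1)
  expect_gt(fit$metrics$r2, 0.99)
  expect_lt(fit$metrics$mae, 0.01)
  expect_true(all(fit$p_values <= 0.05))
  # the methods work
  expect_length(coef(fit), 3)
  expect_equal(predict(fit, x, type = "committor"),
               as.numeric(logistic_std(fit, x)), tolerance = 1e-12)
  expect_equal(fitted(fit) + residuals(fit), ds$records$p)
  expect_output(print(fit), "reaction coordinate")
  expect_output(print(summary(fit)), "bootstrap")
  sim <- simulate(fit, seed = 1)
  expect_true(all(sim$p_sim >= 0 & sim$p_sim <= 1))
})

test_that("transition-state diagnostics find the 0.5 peak for a true model", {
  set.seed(15)
  z <- stats::runif(600, -6, 6)
  p <- 1 / (1 + exp(-z))
  d <- ts_diagnostics(p, z)
  expect_lte(abs(d$peak_bin_mid - 0.5), 0.051)
  expect_equal(d$mean_committor, 0.5, tolerance = 0.05)
  expect_equal(d$sign_consistency_s1, 1)
  expect_equal(d$sign_consistency_closed, 1)
  # a vacuous stripe reproduces the full histogram
  wide <- ts_diagnostics(p, z, stripe = c(-10, 10))
  expect_equal(sum(wide$histogram$counts), 600)
  expect_error(ts_diagnostics(p, z, stripe = c(99, 100)), "stripe")
})

test_that("splitting the CV conserves the full coordinate", {
  set.seed(16)
  n <- 200
  x <- matrix(stats::rnorm(n * 4), n, dimnames = list(NULL, paste0("f", 1:4)))
  p <- as.numeric(1 / (1 + exp(-(x[, 1] + x[, 2] - x[, 3] - 0.5 * x[, 4]))))
  ds <- committor_dataset(data.frame(id = seq_len(n), p = p), x)
  ds <- stratified_partition(ds, test_count = 10, seed = 17)
  fit <- finalize_coefficients(ds, paste0("f", 1:4), n_boot = 40, seed = 18)
  sp <- split_cv(fit, x, gamma = 0.2, seed = 19)
  expect_setequal(c(sp$part1$features, sp$part2$features), paste0("f", 1:4))
  z_full <- predict(fit, x, type = "cv")
  expect_equal(sp$series1 + sp$series2, z_full, tolerance = 1e-10)
  expect_true(is.na(sp$r) || abs(sp$r) <= 1)
  # forcing everything into one part leaves the other empty and flagged
  cl <- sp$clusters
  grouping <- stats::setNames(rep(1L, length(unique(cl))),
                              as.character(sort(unique(cl))))
  expect_warning(sp1 <- split_cv(fit, x, gamma = 0.2, grouping = grouping,
                                 seed = 19), "empty")
  expect_true(all(sp1$series2 == 0))
  expect_true(is.na(sp1$r))
})

test_that("the optimized RC collapses to one linear CV over raw features", {
  set.seed(20)
  n <- 250
  raw <- cbind(a1 = stats::rnorm(n), a2 = stats::rnorm(n),
               b1 = stats::rnorm(n))
  raw[, "a2"] <- raw[, "a1"] + stats::rnorm(n, sd = 0.1)
  p <- as.numeric(1 / (1 + exp(-(raw[, "a1"] - raw[, "b1"]))))
  cl <- correlation_cluster(raw, gamma = 0.3, seed = 21)
  red <- cluster_pc1_reduce(raw, cl)
  series <- reduce_transform(red, raw)
  ds <- committor_dataset(data.frame(id = seq_len(n), p = p), series)
  ds <- stratified_partition(ds, test_count = 10, seed = 22)
  fit <- finalize_coefficients(ds, colnames(series), n_boot = 40, seed = 23)
  lin <- rc_as_linear_cv(fit, red)
  expect_equal(predict(lin, raw), predict(fit, series, type = "cv"),
               tolerance = 1e-8)
})
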