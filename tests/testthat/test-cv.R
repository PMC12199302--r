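make_fm <- function(vals) {
  feature_matrix(seq_len(nrow(vals)), vals,
                 data.frame(name = colnames(vals), kind = "synthetic"))
}

test_that("PCA reduction reports variance shares and enforces rank", {
  sig <- seq(-3, 3, length.out = 50)
  rank1 <- make_fm(cbind(a = sig, b = 2 * sig, c = -sig))
  pr <- pca_reduce(rank1, 1)
  expect_equal(pr$cum_var_share, 1)
  expect_error(pca_reduce(rank1, 2), "rank")
  expect_error(pca_reduce(rank1, 0))
  set.seed(6)
  iso <- make_fm(cbind(a = stats::rnorm(4000), b = stats::rnorm(4000)))
  pr2 <- pca_reduce(iso, 2)
  expect_equal(pr2$var_share[1], 0.5, tolerance = 0.05)
  expect_equal(pr2$cum_var_share, 1)
})

sep_clouds <- function(n = 100, seed = 7) {
  set.seed(seed)
  x <- rbind(cbind(stats::rnorm(n, -3, 0.5), stats::rnorm(n, 0, 0.5)),
             cbind(stats::rnorm(n, 3, 0.5), stats::rnorm(n, 0, 0.5)))
  colnames(x) <- c("f1", "f2")
  list(fm = make_fm(x), labels = rep(c("closed", "S1"), each = n))
}

test_that("the SVM CV separates labelled clouds with the S1 side positive", {
  sc <- sep_clouds()
  cv <- fit_svm_cv(pca_reduce(sc$fm, 2), sc$labels)
  expect_equal(attr(cv, "training_accuracy"), 1)
  z <- predict(cv, sc$fm)
  expect_true(all(z[sc$labels == "S1"] > 0))
  expect_true(all(z[sc$labels == "closed"] < 0))
  # swapping the classes flips the sign convention target, so |CV| match
  cv2 <- fit_svm_cv(pca_reduce(sc$fm, 2),
                    ifelse(sc$labels == "S1", "closed", "S1"))
  expect_equal(abs(predict(cv2, sc$fm)), abs(z), tolerance = 1e-6)
  expect_error(fit_svm_cv(pca_reduce(sc$fm, 2),
                          rep("closed", nrow(sc$fm$values))), "both classes")
})

test_that("the SVM CV is invariant to rescaling a raw feature", {
  sc <- sep_clouds()
  cv1 <- fit_svm_cv(pca_reduce(sc$fm, 2), sc$labels)
  scaled <- sc$fm
  scaled$values[, 1] <- scaled$values[, 1] * 1000
  cv2 <- fit_svm_cv(pca_reduce(scaled, 2), sc$labels)
  expect_equal(predict(cv1, sc$fm), predict(cv2, scaled), tolerance = 1e-8)
})

test_that("terminal-window labelling marks path ends only", {
  lab <- label_terminal_frames(rep(1:2, each = 30), frac = 0.10)
  expect_equal(sum(lab == "closed", na.rm = TRUE), 6)
  expect_equal(sum(lab == "S1", na.rm = TRUE), 6)
  expect_equal(lab[1:3], rep("closed", 3))
  expect_equal(lab[58:60], rep("S1", 3))
  expect_true(all(is.na(lab[10:20])))
})

test_that("state assignment partitions with half-open boxes", {
  def <- state_definition(closed = c(0, 1, 0, 1), s1 = c(2, 3, 0, 1),
                          reactive = c(1, 2, 0, 1))
  pts <- rbind(c(0.5, 0.5), c(2.5, 0.5), c(1.5, 0.5), c(5, 5),
               c(1, 0.5),   # shared edge: belongs to the right-hand box
               c(0, 0))     # lower-left corner inclusive
  expect_equal(assign_state(pts, def),
               c("closed", "S1", "reactive", "outside", "reactive",
                 "closed"))
  expect_error(state_definition(c(0, 1, 0, 1), c(0.5, 2, 0, 1),
                                c(3, 4, 0, 1)), "disjoint")
})

test_that("density regions recover two clouds and a bridging rectangle", {
  set.seed(8)
  a <- cbind(stats::rnorm(2000, -4, 0.4), stats::rnorm(2000, 0, 0.4))
  b <- cbind(stats::rnorm(2000, 4, 0.4), stats::rnorm(2000, 0, 0.4))
  bridge <- cbind(stats::runif(60, -2, 2), stats::rnorm(60, 0, 0.3))
  def <- density_regions(rbind(a, b, bridge), bins = 60)
  expect_s3_class(def, "state_definition")
  lab <- assign_state(bridge, def)
  expect_gt(mean(lab == "reactive"), 0.8)
  expect_equal(unique(assign_state(matrix(c(-4, 0), 1), def)), "closed")
  expect_equal(unique(assign_state(matrix(c(4, 0), 1), def)), "S1")
  # a single dense cloud has no second component
  set.seed(9)
  one <- cbind(stats::rnorm(20000, 0, 0.4), stats::rnorm(20000, 0, 0.4))
  expect_error(density_regions(one, bins = 30), "fewer than two")
})

test_that("linear CVs survive a JSON round trip", {
  cv <- linear_cv(c("a", "b"), c(1, 2), c(0.5, 2), c(0.3, -0.7), 0.1,
                  provenance = list(stage = "svm_cv"))
  path <- tempfile(fileext = ".json")
  write_cv_json(cv, path)
  cv2 <- read_cv_json(path)
  newx <- matrix(stats::rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(predict(cv2, newx), predict(cv, newx))
})
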