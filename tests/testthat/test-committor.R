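dw2 <- potential_double_well(barrier_height = 4, dimensionality = 2)
states <- interval_states(-0.7, 0.7)

test_that("shooting from committed snapshots returns degenerate committors", {
  cfg <- shooting_config(n_shots = 50)
  expect_equal(shoot(c(-1, 0), dw2, states, cfg, seed = 1)$p, 0)
  expect_equal(shoot(c(1, 0), dw2, states, cfg, seed = 1)$p, 1)
})

test_that("shot counts always add up and records are reproducible", {
  cfg <- shooting_config(n_shots = 200, max_steps = 2000)
  r <- shoot(c(0.1, 0), dw2, states, cfg, seed = 3)
  expect_equal(r$n_to_s1 + r$n_to_closed + r$n_uncommitted, r$n_shots)
  r2 <- shoot(c(0.1, 0), dw2, states, cfg, seed = 3)
  expect_identical(r$p, r2$p)
})

test_that("the saddle committor agrees with the symmetric oracle", {
  cfg <- shooting_config(n_shots = 2000, max_steps = 4000, timestep = 0.005)
  r <- shoot(c(0, 0), dw2, states, cfg, seed = 5)
  expect_equal(r$p, 0.5, tolerance = 0.035)  # 3 sigma binomial at n = 2000
})

make_dataset <- function(p, seed = 1) {
  set.seed(seed)
  feats <- matrix(stats::rnorm(2 * length(p)), ncol = 2,
                  dimnames = list(NULL, c("f1", "f2")))
  committor_dataset(data.frame(id = seq_along(p), p = p), feats)
}

test_that("stratified partitioning draws equal test counts per bin", {
  p <- rep(seq(0.05, 0.95, 0.1), each = 10)   # 100 records, uniform bins
  ds <- stratified_partition(make_dataset(p), test_count = 20,
                             validation_frac = 0.1, seed = 2)
  tab <- table(ds$records$bin[ds$records$split == "test"])
  expect_equal(as.numeric(tab), rep(2, 10))
  expect_true(all(c("test", "validation", "training") %in%
                    ds$records$split))
  expect_error(stratified_partition(make_dataset(rep(0, 100)), 20),
               "empty committor bin")
})

test_that("stratified bootstrap preserves bin proportions and pool size", {
  p <- rep(seq(0.05, 0.95, 0.1), each = 10)
  ds <- make_dataset(p)
  pool <- seq_len(100)
  reps <- bootstrap_resample(ds, pool, 5, seed = 3)
  for (r in reps) {
    expect_length(r, 100)
    tab <- table(ds$records$bin[r])
    expect_true(all(abs(as.numeric(tab) - 10) <= 1))
  }
  # a pool of one record bootstraps to that record repeated
  one <- bootstrap_resample(ds, 7L, 1, seed = 4)
  expect_true(all(one[[1]] == 7L))
})

test_that("stratified subsampling flattens a bimodal committor harvest", {
  p <- c(rep(0.01, 400), rep(0.99, 400), stats::runif(100))
  ds <- stratified_subsample(make_dataset(p, seed = 5), 300, seed = 6)
  expect_equal(nrow(ds$records), 300)
  tab <- tabulate(ds$records$bin, 10)
  expect_true(all(tab >= 5))
  expect_lt(max(tab) / max(min(tab), 1), 25)
})

test_that("reactive snapshots are harvested frame-exactly with blacklists", {
  def <- state_definition(closed = c(-2, -1, -1, 1), s1 = c(1, 2, -1, 1),
                          reactive = c(-1, 1, -1, 1))
  proj <- list(cbind(c(-1.5, -0.5, 0, 0.5, 1.5), 0),   # 3 reactive frames
               cbind(c(-1.5, -1.2, 1.2, 1.5), 0))      # none
  snaps <- harvest_reactive_snapshots(proj, def)
  expect_equal(snaps$path_id, c(1, 1, 1))
  expect_equal(snaps$frame, 2:4)
  expect_warning(harvest_reactive_snapshots(proj, def, blacklist = 1:2),
                 "no reactive")
})

test_that("committor datasets survive a TSV round trip", {
  p <- stats::runif(40)
  ds <- make_dataset(p, seed = 7)
  path <- tempfile(fileext = ".tsv")
  write_committor_tsv(ds, path)
  ds2 <- read_committor_tsv(path)
  expect_equal(ds2$records$p, ds$records$p)
  expect_equal(ds2$features, ds$features)
  expect_equal(ds2$n_bins, ds$n_bins)
})
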