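test_that("double-well potential has the stated wells and barrier", {
  pot <- potential_double_well(barrier_height = 4, well_positions = c(-1, 1))
  expect_equal(pot$energy(-1), 0)
  expect_equal(pot$energy(1), 0)
  expect_equal(pot$energy(0), 4)
  expect_equal(pot$gradient(0), 0)
  expect_equal(pot$gradient(-1), 0)
})

test_that("zero-temperature dynamics stays at a potential minimum", {
  pot <- potential_double_well(barrier_height = 4)
  par <- langevin_params(timestep = 0.01, kT = 0, n_steps = 500L, seed = 1L)
  tr <- simulate_overdamped(pot, par, -1)
  expect_true(all(abs(tr$coords[, 1] + 1) < 1e-12))
})

test_that("harmonic sampling reproduces the equipartition variance kT/k", {
  pot <- potential_harmonic(stiffness = 4)
  par <- langevin_params(timestep = 0.005, kT = 1, n_steps = 200000L,
                         save_interval = 10L, seed = 3L)
  tr <- simulate_overdamped(pot, par, 0)
  expect_equal(stats::var(tr$coords[, 1]), 0.25, tolerance = 0.05)
})

test_that("identical seeds give bit-identical trajectories", {
  pot <- potential_double_well(barrier_height = 2, dimensionality = 2)
  par <- langevin_params(n_steps = 2000L, seed = 42L)
  t1 <- simulate_overdamped(pot, par, c(-1, 0))
  t2 <- simulate_overdamped(pot, par, c(-1, 0))
  expect_identical(t1$coords, t2$coords)
})

test_that("long unbiased runs satisfy detailed balance against exp(-U/kT)", {
  pot <- potential_double_well(barrier_height = 1)
  par <- langevin_params(timestep = 0.01, n_steps = 500000L,
                         save_interval = 100L, seed = 7L)
  tr <- simulate_overdamped(pot, par, -1)
  x <- tr$coords[, 1]
  edges <- seq(-1.8, 1.8, length.out = 25)
  x <- x[x > edges[1] & x < edges[length(edges)]]
  counts <- table(cut(x, edges))
  probs <- vapply(seq_len(length(edges) - 1), function(i)
    stats::integrate(function(y) exp(-vapply(y, pot$energy, numeric(1))),
                     edges[i], edges[i + 1])$value, numeric(1))
  keep <- probs / sum(probs) * length(x) >= 5
  ct <- suppressWarnings(stats::chisq.test(as.numeric(counts)[keep],
                                           p = probs[keep] / sum(probs[keep])))
  expect_gt(ct$p.value, 0.01)
})

test_that("the 1D committor oracle matches closed forms", {
  dw <- potential_double_well(barrier_height = 4)
  expect_equal(analytic_committor_1d(dw, -0.7, 0.7, 0), 0.5)
  flat <- potential_flat()
  expect_equal(analytic_committor_1d(flat, 0, 1, 0.25), 0.25,
               tolerance = 1e-8)
  # tilted linear potential: q(x) = (e^{cx} - e^{ca}) / (e^{cb} - e^{ca})
  cc <- 1.5
  lin <- potential_custom(function(x) cc * x[1],
                          function(x) cc, dimensionality = 1)
  for (x in c(-0.5, 0, 0.3)) {
    expect_equal(analytic_committor_1d(lin, -1, 1, x),
                 (exp(cc * x) - exp(-cc)) / (exp(cc) - exp(-cc)),
                 tolerance = 1e-6)
  }
})

test_that("transition path generation yields committed reactive paths", {
  sys <- benchmark_system()
  paths <- generate_transition_paths(sys$potential, sys$params,
                                     sys$state_bounds, 4L, seed = 5L)
  expect_gt(length(paths), 0)
  for (p in paths) {
    x1 <- p$coords[, 1]
    expect_true(x1[1] >= sys$state_bounds$closed[1] &&
                  x1[1] <= sys$state_bounds$closed[2])
    expect_true(x1[length(x1)] >= sys$state_bounds$s1[1] &&
                  x1[length(x1)] <= sys$state_bounds$s1[2])
  }
  empty <- generate_transition_paths(sys$potential, sys$params,
                                     sys$state_bounds, 0L)
  expect_length(empty, 0)
})

test_that("first-passage slows with barrier height (Kramers direction)", {
  first_passage <- function(barrier, seed) {
    pot <- potential_double_well(barrier_height = barrier)
    st <- interval_states(-0.7, 0.7)
    mean(replicate(20, {
      seed <<- seed + 1L
      set.seed(seed)
      r <- propagate_committed(pot, matrix(-1, 1, 1), -Inf, 0.7,
                               0.01, 1, 1, 60000L)
      r$steps[1]
    }), na.rm = TRUE)
  }
  expect_gt(first_passage(4, 100L), first_passage(2, 200L))
})

test_that("feature embedding carries the planted structure", {
  pot <- potential_flat()
  par <- langevin_params(timestep = 0.01, n_steps = 9999L, seed = 2L)
  traj <- simulate_overdamped(pot, par, 0)
  spec <- feature_embedding_spec(n_informative = 2, n_decoy = 10,
                                 collinear_blocks = list(c(5, 0.95)),
                                 link = "linear", noise_sd = 0,
                                 seed = 9L)
  fm <- embed_features(traj, spec, noise_seed = 11L)
  expect_equal(nrow(fm$values), 10000L)
  # noiseless linear link: feature is an exact affine image of the latent x
  expect_equal(abs(stats::cor(fm$values[, "inf001"], traj$coords[, 1])), 1)
  # collinear block: pairwise |r| above 0.9 at the 0.95 target
  blk <- fm$values[, fm$meta$block == 1]
  cm <- abs(stats::cor(blk))
  expect_true(all(cm[upper.tri(cm)] > 0.9))
  # decoys are independent of the latent coordinate
  dcy <- fm$values[, fm$meta$role == "decoy" & fm$meta$block == 0]
  expect_true(all(abs(stats::cor(dcy, traj$coords[, 1])) < 0.1))
  # determinism
  fm2 <- embed_features(traj, spec, noise_seed = 11L)
  expect_identical(fm$values, fm2$values)
})

test_that("embedding mean map matches the noiseless embedding", {
  pot <- potential_flat()
  par <- langevin_params(timestep = 0.01, n_steps = 50L, seed = 2L)
  traj <- simulate_overdamped(pot, par, 0)
  spec <- feature_embedding_spec(n_informative = 3, n_decoy = 2,
                                 collinear_blocks = list(), noise_sd = 0,
                                 seed = 4L)
  fm <- embed_features(traj, spec)
  mm <- embedding_mean_map(spec, c("inf001", "inf003"))
  expect_equal(mm$value(traj$coords[, 1])[, "inf001"],
               unname(fm$values[, "inf001"]))
  # derivative agrees with finite differences
  x <- seq(-1, 1, 0.2)
  fd <- (mm$value(x + 1e-6) - mm$value(x - 1e-6)) / 2e-6
  expect_equal(mm$deriv(x), fd, tolerance = 1e-5)
})
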