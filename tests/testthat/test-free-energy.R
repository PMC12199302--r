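ident_cv <- list(value = function(x) x, deriv = function(x) rep(1, length(x)))

test_that("window seeds are nearest path frames within one width", {
  series <- list(seq(-2, 0, 0.1), seq(0, 2, 0.1))
  seeds <- select_window_seeds(series, centers = c(-1, 0, 1), width = 0.5)
  expect_equal(nrow(seeds), 3)
  expect_true(all(abs(seeds$cv - c(-1, 0, 1)) <= 0.05))
  expect_error(select_window_seeds(series, centers = 5, width = 0.5),
               "window width")
})

test_that("biased sampling matches the stiff-spring Gaussian limits", {
  flat <- potential_flat()
  par <- langevin_params(timestep = 0.01)
  w <- umbrella_window_spec(center = 1, force_constant = 8,
                            equilibration = 2, production = 100)
  z <- run_biased_sampling(flat, par, ident_cv, w, x0 = 1, seed = 1)
  expect_equal(stats::var(z), 1 / 8, tolerance = 0.15)   # kT / k
  expect_equal(mean(z), 1, tolerance = 0.05)
  z2 <- run_biased_sampling(flat, langevin_params(timestep = 0.001),
                            ident_cv,
                            umbrella_window_spec(1, force_constant = 500,
                                                 equilibration = 1,
                                                 production = 10),
                            x0 = 1, seed = 2)
  expect_equal(mean(z2), 1, tolerance = 0.02)
  expect_error(umbrella_window_spec(1, production = 0))
})

test_that("a single unbiased window reduces WHAM to -kT log histogram", {
  pot <- potential_harmonic(stiffness = 4)
  par <- langevin_params(timestep = 0.01)
  z <- run_biased_sampling(pot, par, ident_cv,
                           umbrella_window_spec(0, force_constant = 1e-9,
                                                equilibration = 2,
                                                production = 150),
                           x0 = 0, seed = 3)
  prof <- wham_unbias(list(z), centers = 0, force_constant = 1e-9,
                      bin_width = 0.25)
  edges <- seq(floor(min(z) / 0.25) * 0.25, max(z) + 0.25, 0.25)
  h <- tabulate(findInterval(z, edges, rightmost.closed = TRUE),
                length(edges) - 1)
  manual <- -log(h[h > 0])
  expect_equal(prof$free_energy, manual - min(manual), tolerance = 1e-6)
})

test_that("WHAM recovers a harmonic profile and is stable in window count", {
  pot <- potential_harmonic(stiffness = 2)
  par <- langevin_params(timestep = 0.01)
  scan <- function(centers, seed, production = 60) {
    x0s <- matrix(0, length(centers), 1); x0s[, 1] <- centers
    series <- run_biased_ensemble(pot, par, ident_cv, centers,
                                  force_constant = 10, equilibration = 3,
                                  production = production, x0s, seed = seed)
    wham_unbias(series, centers, force_constant = 10, bin_width = 0.25)
  }
  p1 <- scan(seq(-2, 2, 0.5), seed = 4, production = 150)
  ref <- pot$stiffness / 2 * p1$z^2
  i <- abs(p1$z) <= 2
  resid <- p1$free_energy[i] - ref[i]
  expect_lt(sqrt(mean((resid - mean(resid))^2)), 0.15)  # kT units
  # doubling the windows at fixed coverage barely moves the profile
  p2 <- scan(seq(-2, 2, 0.25), seed = 5, production = 150)
  common <- intersect(round(p1$z[i], 3), round(p2$z, 3))
  f1 <- p1$free_energy[match(common, round(p1$z, 3))]
  f2 <- p2$free_energy[match(common, round(p2$z, 3))]
  expect_lt(mean(abs((f1 - mean(f1)) - (f2 - mean(f2)))), 0.1)
})

test_that("WHAM refuses windows with no histogram overlap", {
  set.seed(6)
  z1 <- stats::rnorm(500, -5, 0.1); z2 <- stats::rnorm(500, 5, 0.1)
  expect_error(wham_unbias(list(z1, z2), c(-5, 5), force_constant = 100,
                           bin_width = 0.25),
               "overlap")
})

test_that("1RT basins follow the closed-form quadratic width", {
  z <- seq(-3, 3, 0.05)
  rt <- 1
  # two quadratic wells of stiffness 2RT at +/- 1.5; the parabolas cross at
  # z = 0 with height 1.5^2 = 2.25, the barrier
  f <- pmin((z + 1.5)^2, (z - 1.5)^2)
  prof <- structure(data.frame(z = z, free_energy = f),
                    class = c("free_energy_profile", "data.frame"))
  bb <- basin_bounds(prof, rt = rt)
  expect_equal(bb$closed, c(-2.5, -0.5), tolerance = 0.06)
  expect_equal(bb$s1, c(0.5, 2.5), tolerance = 0.06)
  expect_equal(bb$barrier_height, 2.25, tolerance = 1e-6)
  # symmetric double well gives mirror-image intervals
  expect_equal(bb$closed, -rev(bb$s1), tolerance = 1e-6)
  # genuinely multimodal profiles are refused
  f3 <- 2 * cos(z * 3) + 0.5 * z^2
  prof3 <- structure(data.frame(z = z, free_energy = f3 - min(f3)),
                     class = c("free_energy_profile", "data.frame"))
  expect_error(basin_bounds(prof3, rt = 1), "multimodal")
})

test_that("basin free-energy differences integrate Boltzmann populations", {
  z <- seq(-3, 3, 0.01)
  f <- pmin((z + 1.5)^2, (z - 1.5)^2)
  prof <- structure(data.frame(z = z, free_energy = f),
                    class = c("free_energy_profile", "data.frame"))
  bb <- basin_bounds(prof, rt = 1)
  expect_equal(free_energy_difference(prof, bb, rt = 1), 0,
               tolerance = 1e-10)
  # planted asymmetry: shift the S1 well down by delta
  delta <- 0.8
  f2 <- pmin((z + 1.5)^2, (z - 1.5)^2 - delta)
  prof2 <- structure(data.frame(z = z, free_energy = f2 - min(f2)),
                     class = c("free_energy_profile", "data.frame"))
  bb2 <- basin_bounds(prof2, rt = 1)
  expect_equal(free_energy_difference(prof2, bb2, rt = 1), -delta,
               tolerance = 0.1)
  expect_error(free_energy_difference(prof, list(closed = c(10, 11),
                                                 s1 = bb$s1), rt = 1),
               "population")
})

test_that("population ratio e gives RT at 320 K", {
  expect_equal(rt_kjmol(320), 8.314462618 * 0.320)
  # -RT ln(1/e) = RT
  z <- c(0, 1)
  prof <- structure(data.frame(z = z, free_energy = c(0, rt_kjmol(320))),
                    class = c("free_energy_profile", "data.frame"))
  d <- free_energy_difference(prof, list(closed = c(-0.1, 0.1),
                                         s1 = c(0.9, 1.1)),
                              rt = rt_kjmol(320))
  expect_equal(d, rt_kjmol(320), tolerance = 1e-10)
})
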