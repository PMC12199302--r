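#' Model potentials for the synthetic benchmark
#'
#' A `model_potential` bundles an energy function, its gradient and a
#' description of the latent space on which the overdamped Langevin engine
#' runs.  Energies are in units of kT unless stated otherwise; the first
#' latent coordinate carries the transition, any further coordinates are
#' harmonic "orthogonal" modes.
#'
#' @param barrier_height Barrier height at the saddle relative to the well
#'   minima, in kT units.  Must be >= 0.
#' @param well_positions Length-two numeric, positions of the two minima on
#'   the transition coordinate (must be distinct).
#' @param tilt Energy difference added linearly across the two wells
#'   (kT units); positive values lower the second well.
#' @param orthogonal_stiffness Harmonic stiffness of each non-transition
#'   coordinate (kT per squared length unit).
#' @param dimensionality Number of latent coordinates (>= 1).
#' @return An object of class `model_potential` with elements `energy(x)`,
#'   `gradient(x)`, `form`, `dimensionality`, `well_positions`,
#'   `barrier_height`, `domain`.
#' @details The double well is the standard quartic
#'   \eqn{U(x) = B ((x - m)^2/h^2 - 1)^2 - t (x - m)/(2 h)} rescaled so the
#'   minima sit at `well_positions` and the saddle barrier is
#'   `barrier_height` when `tilt = 0`.
#' @export
potential_double_well <- function(barrier_height = 4, well_positions = c(-1, 1),
                                  tilt = 0, orthogonal_stiffness = 4,
                                  dimensionality = 1) {
  stopifnot(barrier_height >= 0, length(well_positions) == 2,
            well_positions[1] != well_positions[2], dimensionality >= 1)
  m <- mean(well_positions)
  h <- abs(diff(well_positions)) / 2
  B <- barrier_height
  kappa <- orthogonal_stiffness
  energy <- function(x) {
    x <- as_latent_point(x, dimensionality)
    u <- (x[1] - m) / h
    e <- B * (u^2 - 1)^2 - tilt * u / 2
    if (dimensionality > 1) e <- e + 0.5 * kappa * sum(x[-1]^2)
    e
  }
  gradient <- function(x) {
    x <- as_latent_point(x, dimensionality)
    u <- (x[1] - m) / h
    g <- numeric(dimensionality)
    g[1] <- (4 * B * u * (u^2 - 1) - tilt / 2) / h
    if (dimensionality > 1) g[-1] <- kappa * x[-1]
    g
  }
  structure(list(form = "double-well", energy = energy, gradient = gradient,
                 dimensionality = dimensionality,
                 well_positions = sort(well_positions),
                 barrier_height = barrier_height, tilt = tilt,
                 orthogonal_stiffness = orthogonal_stiffness,
                 domain = c(-Inf, Inf)),
            class = "model_potential")
}

#' @rdname potential_double_well
#' @param stiffness Harmonic stiffness of the transition coordinate
#'   (kT per squared length).
#' @param center Minimum position.
#' @export
potential_harmonic <- function(stiffness = 4, center = 0,
                               orthogonal_stiffness = stiffness,
                               dimensionality = 1) {
  stopifnot(stiffness > 0, dimensionality >= 1)
  energy <- function(x) {
    x <- as_latent_point(x, dimensionality)
    e <- 0.5 * stiffness * (x[1] - center)^2
    if (dimensionality > 1) e <- e + 0.5 * orthogonal_stiffness * sum(x[-1]^2)
    e
  }
  gradient <- function(x) {
    x <- as_latent_point(x, dimensionality)
    g <- numeric(dimensionality)
    g[1] <- stiffness * (x[1] - center)
    if (dimensionality > 1) g[-1] <- orthogonal_stiffness * x[-1]
    g
  }
  structure(list(form = "harmonic", energy = energy, gradient = gradient,
                 dimensionality = dimensionality, stiffness = stiffness,
                 center = center, orthogonal_stiffness = orthogonal_stiffness,
                 barrier_height = 0, well_positions = c(center, center),
                 domain = c(-Inf, Inf)),
            class = "model_potential")
}

#' @rdname potential_double_well
#' @export
potential_flat <- function(dimensionality = 1) {
  energy <- function(x) 0
  gradient <- function(x) numeric(dimensionality)
  structure(list(form = "flat", energy = energy, gradient = gradient,
                 dimensionality = dimensionality, barrier_height = 0,
                 well_positions = c(NA_real_, NA_real_),
                 domain = c(-Inf, Inf)),
            class = "model_potential")
}

#' @rdname potential_double_well
#' @param energy_fun Function of a latent point returning energy (kT units).
#' @param gradient_fun Function returning the gradient vector; when `NULL` a
#'   central finite difference is used.
#' @param form Label stored on the object.
#' @export
potential_custom <- function(energy_fun, gradient_fun = NULL,
                             dimensionality = 1, form = "user-tabulated") {
  stopifnot(is.function(energy_fun))
  if (is.null(gradient_fun)) {
    gradient_fun <- function(x) {
      eps <- 1e-6
      vapply(seq_len(dimensionality), function(i) {
        e <- numeric(dimensionality); e[i] <- eps
        (energy_fun(x + e) - energy_fun(x - e)) / (2 * eps)
      }, numeric(1))
    }
  }
  structure(list(form = form, energy = energy_fun, gradient = gradient_fun,
                 dimensionality = dimensionality, barrier_height = NA_real_,
                 well_positions = c(NA_real_, NA_real_),
                 domain = c(-Inf, Inf)),
            class = "model_potential")
}

as_latent_point <- function(x, d) {
  x <- as.numeric(x)
  if (length(x) == 1 && d > 1) x <- c(x, numeric(d - 1))
  stopifnot(length(x) == d)
  x
}

#' @export
print.model_potential <- function(x, ...) {
  cat("<model_potential>", x$form, "in", x$dimensionality, "latent dim(s)\n")
  if (x$form == "double-well")
    cat("  wells at", x$well_positions[1], "and", x$well_positions[2],
        "; barrier", x$barrier_height, "kT; tilt", x$tilt, "kT\n")
  invisible(x)
}

#' Exact committor of one-dimensional overdamped diffusion
#'
#' For an overdamped diffusion on a 1D potential the probability of reaching
#' `b` before `a` from `x` is
#' \deqn{q(x) = \int_a^x e^{U/kT} \, dy \Big/ \int_a^b e^{U/kT} \, dy.}
#' Used throughout as the brute-force oracle for shooting estimates.
#'
#' @param potential A 1D `model_potential`.
#' @param a,b Absorbing boundaries, `a < b` (reactant / product side).
#' @param x Evaluation point(s), each in `(a, b)`.
#' @param kT Thermal energy in the potential's energy units.
#' @return Committor probabilities, same length as `x`.
#' @export
analytic_committor_1d <- function(potential, a, b, x, kT = 1) {
  stopifnot(inherits(potential, "model_potential"),
            potential$dimensionality == 1, a < b, all(x >= a), all(x <= b),
            kT > 0)
  # subtract the max energy on [a,b] before exponentiating for stability
  grid <- seq(a, b, length.out = 512)
  umax <- max(vapply(grid, potential$energy, numeric(1)))
  f <- function(y) {
    vapply(y, function(yi) exp((potential$energy(yi) - umax) / kT), numeric(1))
  }
  denom <- stats::integrate(f, a, b, rel.tol = 1e-9, subdivisions = 500L)
  if (denom$message != "OK" || !is.finite(denom$value) || denom$value <= 0)
    stop("quadrature for the committor normalization failed: ", denom$message)
  vapply(x, function(xi) {
    if (xi <= a) return(0)
    if (xi >= b) return(1)
    num <- stats::integrate(f, a, xi, rel.tol = 1e-9, subdivisions = 500L)
    if (num$message != "OK") stop("quadrature failed at x = ", xi)
    min(max(num$value / denom$value, 0), 1)
  }, numeric(1))
}

#' Analytic marginal free energy along the transition coordinate
#'
#' Returns \eqn{F(x) = -kT \log \int e^{-U(x, y)/kT} dy} on a grid, anchored
#' so the global minimum is zero.  For potentials that are separable in the
#' orthogonal modes this equals the 1D profile of the transition coordinate.
#'
#' @inheritParams analytic_committor_1d
#' @param grid Numeric grid of transition-coordinate values.
#' @return Data frame with columns `x` and `free_energy` (same units as kT).
#' @export
analytic_marginal_free_energy <- function(potential, grid, kT = 1) {
  stopifnot(inherits(potential, "model_potential"))
  u <- vapply(grid, function(g) {
    x <- numeric(potential$dimensionality); x[1] <- g
    potential$energy(x)
  }, numeric(1))
  f <- u - min(u)
  data.frame(x = grid, free_energy = f)
}
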