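#' Parameters of the overdamped Langevin engine
#'
#' The engine integrates \eqn{\gamma \dot x = -\nabla U + \sqrt{2\gamma kT}\,\xi}
#' with the Euler--Maruyama scheme
#' \eqn{x_{n+1} = x_n - (\Delta t/\gamma)\nabla U(x_n) + \sqrt{2 kT \Delta t/\gamma}\, \eta_n}.
#' Time units are arbitrary simulation units; all kinetics downstream carry
#' the units of the time stamps produced here.
#'
#' @param timestep Integration step (time units), > 0.
#' @param friction Friction coefficient (inverse time), > 0.
#' @param kT Thermal energy in the potential's energy units.
#' @param n_steps Number of integration steps.
#' @param save_interval Save every `save_interval`-th step (>= 1).
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @return A `langevin_params` list.
#' @export
langevin_params <- function(timestep = 0.01, friction = 1, kT = 1,
                            n_steps = 10000L, save_interval = 1L, seed = 1L) {
  stopifnot(timestep > 0, friction > 0, kT >= 0, n_steps >= 1,
            save_interval >= 1)
  structure(list(timestep = timestep, friction = friction, kT = kT,
                 n_steps = as.integer(n_steps),
                 save_interval = as.integer(save_interval),
                 seed = as.integer(seed)),
            class = "langevin_params")
}

#' Simulate an overdamped Langevin trajectory
#'
#' @param potential A `model_potential`.
#' @param params A `langevin_params`.
#' @param x0 Starting latent point (length = dimensionality, or scalar).
#' @return A `latent_trajectory`: list with `times` (strictly increasing) and
#'   `coords` (frames x dimensionality matrix, includes the initial frame).
#' @export
simulate_overdamped <- function(potential, params, x0) {
  stopifnot(inherits(potential, "model_potential"),
            inherits(params, "langevin_params"))
  d <- potential$dimensionality
  x <- as_latent_point(x0, d)
  if (!is.finite(potential$energy(x)))
    stop("non-finite energy at the starting point")
  dt <- params$timestep
  mob <- dt / params$friction
  sig <- sqrt(2 * params$kT * dt / params$friction)
  n_saved <- params$n_steps %/% params$save_interval + 1L
  coords <- matrix(NA_real_, n_saved, d)
  times <- numeric(n_saved)
  coords[1L, ] <- x
  saved <- 1L
  set.seed(params$seed)
  noise <- if (sig > 0) matrix(stats::rnorm(params$n_steps * d), params$n_steps, d)
           else matrix(0, params$n_steps, d)
  for (step in seq_len(params$n_steps)) {
    g <- potential$gradient(x)
    if (any(!is.finite(g)))
      stop("non-finite gradient at step ", step, " (x = ",
           paste(signif(x, 4), collapse = ", "), ")")
    x <- x - mob * g + sig * noise[step, ]
    if (!is.finite(potential$energy(x)))
      stop("non-finite energy at step ", step)
    if (step %% params$save_interval == 0L) {
      saved <- saved + 1L
      coords[saved, ] <- x
      times[saved] <- step * dt
    }
  }
  structure(list(times = times[seq_len(saved)],
                 coords = coords[seq_len(saved), , drop = FALSE],
                 params = params),
            class = "latent_trajectory")
}

#' @export
print.latent_trajectory <- function(x, ...) {
  cat("<latent_trajectory>", nrow(x$coords), "frames x", ncol(x$coords),
      "dim(s); t in [", x$times[1], ",", x$times[length(x$times)], "]\n")
  invisible(x)
}

# Propagate an ensemble of walkers until each is absorbed at x1 <= lower or
# x1 >= upper on the transition coordinate, or until max_steps.  Vectorized
# across walkers.  Returns outcome codes (-1 lower, +1 upper, 0 uncommitted)
# and absorption step indices.  Gradient must be evaluable on a matrix of
# rows; we loop coordinates but vectorize walkers for the standard forms.
propagate_committed <- function(potential, x0_matrix, lower, upper,
                                timestep, friction, kT, max_steps) {
  d <- potential$dimensionality
  n <- nrow(x0_matrix)
  grad_mat <- vectorized_gradient(potential)
  x <- x0_matrix
  mob <- timestep / friction
  sig <- sqrt(2 * kT * timestep / friction)
  outcome <- integer(n)
  steps_to <- rep(NA_integer_, n)
  active <- which(x[, 1] > lower & x[, 1] < upper)
  outcome[x0_matrix[, 1] <= lower] <- -1L
  outcome[x0_matrix[, 1] >= upper] <- 1L
  steps_to[outcome != 0L] <- 0L
  for (step in seq_len(max_steps)) {
    if (length(active) == 0L) break
    xa <- x[active, , drop = FALSE]
    g <- grad_mat(xa)
    xa <- xa - mob * g +
      sig * matrix(stats::rnorm(length(active) * d), length(active), d)
    x[active, ] <- xa
    hit_lo <- xa[, 1] <= lower
    hit_hi <- xa[, 1] >= upper
    if (any(hit_lo | hit_hi)) {
      done <- active[hit_lo | hit_hi]
      outcome[active[hit_lo]] <- -1L
      outcome[active[hit_hi]] <- 1L
      steps_to[done] <- step
      active <- active[!(hit_lo | hit_hi)]
    }
  }
  list(outcome = outcome, steps = steps_to, final = x)
}

# Matrix-vectorized gradient for the built-in potential forms; falls back to
# a row-wise loop for custom potentials.
vectorized_gradient <- function(potential) {
  d <- potential$dimensionality
  if (potential$form == "double-well") {
    m <- mean(potential$well_positions)
    h <- abs(diff(potential$well_positions)) / 2
    B <- potential$barrier_height
    tilt <- potential$tilt
    kappa <- potential$orthogonal_stiffness
    function(xm) {
      u <- (xm[, 1] - m) / h
      g <- xm
      g[, 1] <- (4 * B * u * (u^2 - 1) - tilt / 2) / h
      if (d > 1) g[, -1] <- kappa * xm[, -1, drop = FALSE]
      g
    }
  } else if (potential$form == "harmonic") {
    k1 <- potential$stiffness
    kap <- potential$orthogonal_stiffness
    ctr <- potential$center
    function(xm) {
      g <- xm
      g[, 1] <- k1 * (xm[, 1] - ctr)
      if (d > 1) g[, -1] <- kap * xm[, -1, drop = FALSE]
      g
    }
  } else if (potential$form == "flat") {
    function(xm) xm * 0
  } else {
    function(xm) t(apply(xm, 1, potential$gradient))
  }
}

#' Generate reactive transition paths between two wells
#'
#' Runs independent walkers started in well A and keeps, for each walker, the
#' segment from its last departure out of the A-state interval to its first
#' entry into the B-state interval, i.e. a reactive path committed at both
#' ends.  Walkers that do not react within `max_steps` are skipped with a
#' warning.
#'
#' @param potential A `model_potential`.
#' @param params A `langevin_params`; `n_steps` is the per-path step budget.
#' @param state_bounds List with `closed = c(lo, hi)` and `s1 = c(lo, hi)`,
#'   disjoint intervals on the transition coordinate around the two wells.
#' @param n_paths Number of paths requested (0 allowed).
#' @param seed Master seed; per-path seeds are derived and recorded.
#' @param context Number of committed context frames retained on each side
#'   of the reactive segment (0 = bare transit).  The head context lies in
#'   the closed basin by construction; the tail context is truncated before
#'   any re-entry into the closed interval and trimmed so the path ends
#'   inside the S1 interval, so downstream density/labelling stages see
#'   committed frames at both ends.
#' @return List of class `path_ensemble`: each element a `latent_trajectory`
#'   with attributes `path_id` and `seed`.
#' @export
generate_transition_paths <- function(potential, params, state_bounds,
                                      n_paths, seed = 1L, context = 300L) {
  stopifnot(inherits(potential, "model_potential"), n_paths >= 0)
  a <- sort(state_bounds$closed); b <- sort(state_bounds$s1)
  if (a[2] >= b[1] && b[2] >= a[1] && !(a[2] < b[1] || b[2] < a[1]))
    stop("state bounds must be disjoint intervals")
  paths <- list()
  if (n_paths == 0)
    return(structure(paths, class = "path_ensemble"))
  skipped <- 0L
  x_start <- mean(a)
  for (i in seq_len(n_paths)) {
    p <- params
    p$seed <- derive_seed(seed, i)
    traj <- simulate_overdamped(potential, p, x_start)
    x1 <- traj$coords[, 1]
    in_b <- which(x1 >= b[1] & x1 <= b[2])
    if (length(in_b) == 0L) { skipped <- skipped + 1L; next }
    hit_b <- in_b[1]
    before <- which(x1[seq_len(hit_b)] >= a[1] & x1[seq_len(hit_b)] <= a[2])
    start <- if (length(before)) max(before) else 1L
    end <- hit_b
    if (context > 0L) {
      start <- max(1L, start - as.integer(context))
      n <- length(x1)
      lim <- min(n, hit_b + as.integer(context))
      tail_idx <- (hit_b + 1L):lim
      if (hit_b < lim) {
        reenter <- which(x1[tail_idx] >= a[1] & x1[tail_idx] <= a[2])[1]
        if (!is.na(reenter)) tail_idx <- tail_idx[seq_len(reenter - 1L)]
        in_s1 <- which(x1[tail_idx] >= b[1] & x1[tail_idx] <= b[2])
        end <- if (length(in_s1)) tail_idx[max(in_s1)] else hit_b
      }
    }
    seg <- start:end
    paths[[length(paths) + 1L]] <- structure(
      list(times = traj$times[seg], coords = traj$coords[seg, , drop = FALSE],
           params = p),
      class = "latent_trajectory", path_id = length(paths) + 1L,
      seed = p$seed)
  }
  if (skipped > 0L)
    warning(skipped, " of ", n_paths, " walkers showed no transition within ",
            params$n_steps, " steps and were skipped")
  if (length(paths) == 0L)
    stop("no walker reached the product state within the step budget")
  structure(paths, class = "path_ensemble")
}

#' Deterministic master-seed to sub-seed derivation
#'
#' Linear-congruential hash of (master seed, stream index), used everywhere
#' a stage spawns independent random streams; any path, shot or bootstrap
#' replicate is exactly reproducible from the master seed and its index.
#' Results stay below 2^31 - 1.
#'
#' @param master Master seed (integer).
#' @param index Stream index (integer).
#' @return An integer seed.
#' @export
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 16807) %% 2147483647)
}
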