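#' Umbrella window specification
#'
#' @param center Window center in CV units.
#' @param width Window spacing/width in CV units (default 0.5).
#' @param force_constant Harmonic bias strength, energy per CV unit squared,
#'   in the same energy units as the engine `kT` passed to
#'   [run_biased_sampling()] (the structural-scale default of 50 kJ/mol
#'   corresponds to about 18.8 kT at 320 K).
#' @param equilibration,production Simulation time discarded / retained, in
#'   engine time units.
#' @export
umbrella_window_spec <- function(center, width = 0.5, force_constant = 18.8,
                                 equilibration = 5, production = 50) {
  stopifnot(width > 0, force_constant > 0, equilibration >= 0,
            production > 0)
  structure(list(center = center, width = width,
                 force_constant = force_constant,
                 equilibration = equilibration, production = production),
            class = "umbrella_window_spec")
}

#' Pick umbrella seed configurations from existing paths
#'
#' For each window center, returns the path frame whose CV value is nearest;
#' errors when the nearest frame is farther than one window width (the paths
#' do not cover that part of the CV range).
#'
#' @param cv_series List of per-path numeric CV series.
#' @param centers Window centers.
#' @param width Window width used for the gap check.
#' @return Data frame with `center`, `path_id`, `frame`, `cv`.
#' @export
select_window_seeds <- function(cv_series, centers, width = 0.5) {
  all_cv <- unlist(cv_series)
  all_path <- rep(seq_along(cv_series), lengths(cv_series))
  all_frame <- unlist(lapply(cv_series, seq_along))
  out <- lapply(centers, function(ctr) {
    i <- which.min(abs(all_cv - ctr))
    if (abs(all_cv[i] - ctr) > width)
      stop("no path frame within one window width of center ", ctr,
           " (nearest CV value ", signif(all_cv[i], 4), ")")
    data.frame(center = ctr, path_id = all_path[i], frame = all_frame[i],
               cv = all_cv[i])
  })
  do.call(rbind, out)
}

#' Run harmonically biased sampling of a CV on the latent engine
#'
#' Adds the umbrella bias \eqn{\frac{k}{2}(z(x) - c)^2} to the model
#' potential (forces through the chain rule via the CV's latent-coordinate
#' derivative) and returns the production CV series after discarding the
#' equilibration segment.
#'
#' @param potential A `model_potential`.
#' @param params A `langevin_params` (`n_steps` is ignored; step counts
#'   derive from the window's equilibration and production times).
#' @param cvfun List with `value(x)` and `deriv(x)` giving the CV and its
#'   derivative with respect to the transition coordinate (see
#'   [cv_on_latent()]).
#' @param window An `umbrella_window_spec`.
#' @param x0 Starting latent point.
#' @param seed Seed.
#' @return Numeric vector of production-phase CV values, with attribute
#'   `latent` (the matching transition-coordinate values).
#' @export
run_biased_sampling <- function(potential, params, cvfun, window, x0,
                                seed = 1L) {
  stopifnot(inherits(potential, "model_potential"),
            inherits(window, "umbrella_window_spec"))
  if (window$production <= 0) stop("production time must be positive")
  d <- potential$dimensionality
  dt <- params$timestep
  n_eq <- ceiling(window$equilibration / dt)
  n_prod <- ceiling(window$production / dt)
  mob <- dt / params$friction
  sig <- sqrt(2 * params$kT * dt / params$friction)
  k <- window$force_constant
  x <- as_latent_point(x0, d)
  set.seed(seed)
  zs <- numeric(n_prod); xs <- numeric(n_prod)
  for (step in seq_len(n_eq + n_prod)) {
    g <- potential$gradient(x)
    z <- cvfun$value(x[1])
    g[1] <- g[1] + k * (z - window$center) * cvfun$deriv(x[1])
    x <- x - mob * g + sig * stats::rnorm(d)
    if (!is.finite(x[1]))
      stop("biased dynamics diverged at step ", step,
           "; reduce the timestep (stiff bias through a steep CV)")
    if (step > n_eq) {
      zs[step - n_eq] <- cvfun$value(x[1])
      xs[step - n_eq] <- x[1]
    }
  }
  lo <- window$center - window$width; hi <- window$center + window$width
  if (!any(zs >= lo & zs <= hi))
    warning("sampled CV never entered the window around ", window$center)
  attr(zs, "latent") <- xs
  zs
}

#' Run all umbrella windows of one scan simultaneously
#'
#' Vectorized variant of [run_biased_sampling()]: one walker per window, all
#' propagated in lock-step, which makes a full umbrella scan as cheap as a
#' single window.  Identical physics (harmonic bias through the CV's chain
#' rule); per-window series are returned in window order.
#'
#' @param potential A `model_potential`.
#' @param params A `langevin_params` (timestep, friction, kT used).
#' @param cvfun CV map as from [cv_on_latent()] (`value`/`deriv` must be
#'   vectorized).
#' @param centers Window centers.
#' @param force_constant Bias strength (energy per CV unit squared).
#' @param equilibration,production Discarded / retained time per window.
#' @param x0_matrix Starting latent points, one row per window.
#' @param seed Seed.
#' @return List of production CV series, one per window.
#' @export
run_biased_ensemble <- function(potential, params, cvfun, centers,
                                force_constant, equilibration, production,
                                x0_matrix, seed = 1L) {
  d <- potential$dimensionality
  nw <- length(centers)
  x0_matrix <- matrix(as.numeric(x0_matrix), nw, d)
  dt <- params$timestep
  n_eq <- ceiling(equilibration / dt)
  n_prod <- ceiling(production / dt)
  if (n_prod <= 0) stop("production time must be positive")
  mob <- dt / params$friction
  sig <- sqrt(2 * params$kT * dt / params$friction)
  grad_mat <- vectorized_gradient(potential)
  x <- x0_matrix
  out <- matrix(NA_real_, n_prod, nw)
  set.seed(seed)
  for (step in seq_len(n_eq + n_prod)) {
    g <- grad_mat(x)
    z <- cvfun$value(x[, 1])
    g[, 1] <- g[, 1] + force_constant * (z - centers) * cvfun$deriv(x[, 1])
    x <- x - mob * g + sig * matrix(stats::rnorm(nw * d), nw, d)
    if (any(!is.finite(x[, 1])))
      stop("biased dynamics diverged at step ", step,
           "; reduce the timestep (stiff bias through a steep CV)")
    if (step > n_eq) out[step - n_eq, ] <- cvfun$value(x[, 1])
  }
  lapply(seq_len(nw), function(i) out[, i])
}

#' Compose a linear CV with the embedding's deterministic mean map
#'
#' Gives the CV as a smooth function of the latent transition coordinate
#' (noise-free feature values), with its derivative, for use as a biasing
#' coordinate on the synthetic engine.
#'
#' @param cv A `linear_cv` over embedded features.
#' @param spec The `feature_embedding_spec` that generated the features.
#' @param xlim Latent range over which the map is tabulated.
#' @param n_grid Grid size of the spline tabulation.
#' @return List with `value(x)` and `deriv(x)` (vectorized over `x`), plus
#'   `max_slope` (useful for choosing a stable biased timestep).
#' @details The exact map is tabulated once on a fine grid and interpolated
#'   with a cubic spline, so per-step evaluations inside the biased
#'   integrator are cheap; the derivative is the spline derivative.
#' @export
cv_on_latent <- function(cv, spec, xlim = c(-2.5, 2.5), n_grid = 4001) {
  mm <- embedding_mean_map(spec, cv$features)
  exact <- function(x) {
    f <- mm$value(x)
    z <- sweep(sweep(f, 2, cv$scale_mean), 2, cv$scale_sd, "/")
    as.numeric(z %*% cv$weights + cv$intercept)
  }
  grid <- seq(xlim[1], xlim[2], length.out = n_grid)
  sf <- stats::splinefun(grid, exact(grid), method = "natural")
  list(value = function(x) sf(x),
       deriv = function(x) sf(x, deriv = 1),
       max_slope = max(abs(sf(grid, deriv = 1))),
       exact = exact)
}

#' WHAM unbiasing of umbrella-sampled CV series
#'
#' Standard self-consistent weighted-histogram iteration over binned window
#' series: with window biases \eqn{w_i(z) = \frac{k}{2}(z - c_i)^2}, the
#' unbiased probabilities \eqn{P_l} and window free energies \eqn{f_i}
#' are iterated to convergence and the profile is
#' \eqn{F(z_l) = -kT \ln P_l}, anchored at its minimum.
#'
#' @param series List of numeric CV series, one per window.
#' @param centers Window centers aligned with `series`.
#' @param force_constant Bias force constant (energy units of `kT`).
#' @param kT Thermal energy of the sampling engine (default 1).
#' @param bin_width Histogram bin width in CV units (default 0.25).
#' @param tolerance Convergence tolerance on the window free energies.
#' @param max_iter Maximum iterations.
#' @param scale Multiply the output free energies by this factor (e.g.
#'   `rt_kjmol(320) / kT` to report kJ/mol).
#' @return Object of class `free_energy_profile`: data frame `z`,
#'   `free_energy` plus metadata attributes.
#' @export
wham_unbias <- function(series, centers, force_constant, kT = 1,
                        bin_width = 0.25, tolerance = 1e-8, max_iter = 1e5,
                        scale = 1) {
  stopifnot(length(series) == length(centers), length(series) >= 1)
  all_z <- unlist(series)
  edges <- seq(floor(min(all_z) / bin_width) * bin_width,
               max(all_z) + bin_width, by = bin_width)
  mids <- edges[-1] - bin_width / 2
  nb <- length(mids)
  nw <- length(series)
  H <- matrix(0, nw, nb)
  for (i in seq_len(nw)) {
    b <- pmin(pmax(findInterval(series[[i]], edges,
                                rightmost.closed = TRUE), 1L), nb)
    H[i, ] <- tabulate(b, nb)
  }
  if (nw >= 2) {
    ord <- order(centers)
    for (i in seq_len(nw - 1)) {
      a <- H[ord[i], ] > 0; b <- H[ord[i + 1], ] > 0
      if (!any(a & b))
        stop("no histogram overlap between windows at ",
             centers[ord[i]], " and ", centers[ord[i + 1]])
    }
  }
  N <- rowSums(H)
  M <- colSums(H)
  bias <- outer(seq_len(nw), seq_len(nb), function(i, l)
    0.5 * force_constant * (mids[l] - centers[i])^2)
  cmat <- exp(-bias / kT)
  f <- numeric(nw)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    denom <- colSums(N * exp(f / kT) * cmat)   # recycles N, f over rows
    P <- ifelse(denom > 0, M / denom, 0)
    fnew <- -kT * log(pmax(as.numeric(cmat %*% P), .Machine$double.xmin))
    fnew <- fnew - fnew[1]
    resid <- max(abs(fnew - f))
    f <- fnew
    if (resid < tolerance) { converged <- TRUE; break }
  }
  if (!converged)
    stop("WHAM failed to converge within ", max_iter,
         " iterations (residual ", signif(resid, 3), ")")
  denom <- colSums(N * exp(f / kT) * cmat)
  P <- ifelse(denom > 0, M / denom, NA_real_)
  keep <- !is.na(P) & P > 0
  F_kt <- -kT * log(P[keep])
  F_kt <- F_kt - min(F_kt)
  structure(data.frame(z = mids[keep], free_energy = F_kt * scale),
            class = c("free_energy_profile", "data.frame"),
            kT = kT, scale = scale, bin_width = bin_width,
            centers = centers, force_constant = force_constant)
}

#' Average free-energy profiles across replicate paths
#'
#' Interpolates each profile onto a common grid, anchors each at zero in the
#' closed-side minimum, and returns the mean profile with the standard error
#' of the mean across replicates.
#'
#' @param profiles List of `free_energy_profile` objects.
#' @param grid Optional common grid (defaults to the intersection range at
#'   the first profile's spacing).
#' @return A `free_energy_profile` with an extra `sem` column.
#' @export
average_profiles <- function(profiles, grid = NULL) {
  stopifnot(length(profiles) >= 1)
  if (is.null(grid)) {
    lo <- max(vapply(profiles, function(p) min(p$z), numeric(1)))
    hi <- min(vapply(profiles, function(p) max(p$z), numeric(1)))
    step <- diff(profiles[[1]]$z[1:2])
    grid <- seq(lo, hi, by = step)
  }
  F_mat <- vapply(profiles, function(p) {
    f <- stats::approx(p$z, p$free_energy, xout = grid)$y
    f - min(f, na.rm = TRUE)
  }, numeric(length(grid)))
  F_mat <- as.matrix(F_mat)
  m <- rowMeans(F_mat)
  sem <- apply(F_mat, 1, stats::sd) / sqrt(ncol(F_mat))
  out <- data.frame(z = grid, free_energy = m - min(m), sem = sem)
  structure(out, class = c("free_energy_profile", "data.frame"),
            n_replicates = length(profiles))
}

#' @export
plot.free_energy_profile <- function(x, ...) {
  graphics::plot(x$z, x$free_energy, type = "l", xlab = "collective variable",
                 ylab = "free energy", ...)
  if (!is.null(x$sem)) {
    graphics::lines(x$z, x$free_energy + x$sem, lty = 3)
    graphics::lines(x$z, pmax(x$free_energy - x$sem, 0), lty = 3)
  }
  invisible(x)
}

#' Analytic free-energy marginal along a monotone CV, by quadrature
#'
#' Change-of-variables oracle: weights a fine latent grid by
#' \eqn{e^{-U(x)/kT}} and histograms it into CV bins through the map
#' \eqn{z(x)}, giving the exact marginal profile \eqn{-kT \ln p(z)} that a
#' converged umbrella/WHAM estimate along the same CV should recover (the
#' orthogonal modes are separable and contribute a constant).
#'
#' @param potential A `model_potential` (transition coordinate marginal is
#'   used).
#' @param cvfun CV map as from [cv_on_latent()].
#' @param z_grid Bin midpoints (spacing taken from the grid).
#' @param kT Thermal energy.
#' @param xlim Latent integration range.
#' @return A `free_energy_profile` on the populated bins, anchored at 0.
#' @export
analytic_profile_on_cv <- function(potential, cvfun, z_grid, kT = 1,
                                   xlim = c(-2.2, 2.2)) {
  dz <- diff(z_grid[1:2])
  fine <- seq(xlim[1], xlim[2], length.out = 40001)
  u <- vapply(fine, function(g) {
    x <- numeric(potential$dimensionality); x[1] <- g
    potential$energy(x)
  }, numeric(1))
  w <- exp(-(u - min(u)) / kT)
  zf <- cvfun$value(fine)
  edges <- c(z_grid - dz / 2, z_grid[length(z_grid)] + dz / 2)
  b <- findInterval(zf, edges)
  ok <- b >= 1 & b <= length(z_grid)
  pz <- tapply(w[ok], b[ok], sum)
  f <- -kT * log(as.numeric(pz))
  structure(data.frame(z = z_grid[as.integer(names(pz))],
                       free_energy = f - min(f)),
            class = c("free_energy_profile", "data.frame"), kT = kT)
}

#' Define 1RT basins and the barrier from a free-energy profile
#'
#' Locates the single interior maximum between the two minima (the
#' transition state) and returns, on each side, the contiguous interval
#' around the local minimum where the free energy exceeds that minimum by at
#' most `rt` (the 1RT rule for a metastable state).
#'
#' @param profile A `free_energy_profile` (free energy in the same units as
#'   `rt`).
#' @param rt Thermal energy RT in the profile's energy units.
#' @param smooth Odd window length for a running-median smoothing applied
#'   before extremum detection (1 = none).
#' @param prominence A secondary interior maximum only counts as a separate
#'   mode (making the profile multimodal, an error) when the valley between
#'   it and the principal barrier is deeper than this, in `rt` units
#'   (default 0.5); shallower wiggles and flat barrier plateaus are
#'   tolerated.
#' @return List of class `basin_bounds`: `closed`, `s1` (intervals),
#'   `barrier_position`, `barrier_height` (relative to the closed minimum).
#' @export
basin_bounds <- function(profile, rt, smooth = 1, prominence = 0.5) {
  z <- profile$z
  f <- profile$free_energy
  if (smooth > 1) f <- stats::runmed(f, smooth)
  n <- length(f)
  stopifnot(n >= 5)
  interior <- 2:(n - 1)
  is_max <- vapply(interior, function(i) f[i] >= f[i - 1] && f[i] >= f[i + 1]
                   && (f[i] > f[i - 1] || f[i] > f[i + 1]), logical(1))
  maxima <- interior[is_max]
  if (length(maxima) == 0)
    stop("profile has no interior maximum")
  ib <- maxima[which.max(f[maxima])]
  # separate modes = secondary maxima with a deep enough valley in between
  sep <- vapply(maxima, function(m) {
    if (m == ib) return(FALSE)
    valley <- min(f[min(m, ib):max(m, ib)])
    min(f[m], f[ib]) - valley > prominence * rt
  }, logical(1))
  if (any(sep))
    stop("profile is multimodal (", sum(sep) + 1,
         " interior maxima); smooth it or restrict the range")
  left_min <- which.min(f[1:(ib - 1)])
  right_min <- ib + which.min(f[(ib + 1):n])
  sublevel <- function(imin, side) {
    lim <- f[imin] + rt
    idx <- if (side == "left") 1:(ib - 1) else (ib + 1):n
    ok <- f[idx] <= lim
    runs <- rle(ok)
    pos <- cumsum(runs$lengths)
    start <- c(1, utils::head(pos, -1) + 1)
    hit <- which(runs$values &
                   start <= match(imin, idx) & pos >= match(imin, idx))
    sel <- idx[start[hit]:pos[hit]]
    c(z[min(sel)], z[max(sel)])
  }
  structure(list(closed = sublevel(left_min, "left"),
                 s1 = sublevel(right_min, "right"),
                 barrier_position = z[ib],
                 barrier_height = f[ib] - f[left_min],
                 f_ts = f[ib] - f[left_min], rt = rt),
            class = "basin_bounds")
}

#' @export
print.basin_bounds <- function(x, ...) {
  cat("<basin_bounds> closed [", signif(x$closed[1], 4), ",",
      signif(x$closed[2], 4), "]  S1 [", signif(x$s1[1], 4), ",",
      signif(x$s1[2], 4), "]  barrier", signif(x$barrier_height, 4),
      "at z =", signif(x$barrier_position, 4), "\n")
  invisible(x)
}

#' Free-energy difference between basins by histogram integration
#'
#' Integrates the Boltzmann population \eqn{\int e^{-F/RT} dz} over each
#' basin and returns \eqn{\Delta F = -RT \ln(P_{S1}/P_{closed})} (negative
#' when S1 is more favorable).
#'
#' @param profile A `free_energy_profile`.
#' @param basins A `basin_bounds`.
#' @param rt Thermal energy RT in the profile's energy units.
#' @return Free-energy difference in the profile's energy units.
#' @export
free_energy_difference <- function(profile, basins, rt) {
  pop <- function(interval) {
    i <- profile$z >= interval[1] & profile$z <= interval[2]
    if (!any(i)) stop("basin [", interval[1], ", ", interval[2],
                      "] has zero population on the profile grid")
    sum(exp(-profile$free_energy[i] / rt))
  }
  -rt * log(pop(basins$s1) / pop(basins$closed))
}
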