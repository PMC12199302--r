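#' Extract committed transition times from CV path series
#'
#' For each path: the entry time is the first frame inside the closed basin
#' interval; the crossing time is the first later frame beyond the barrier
#' position that subsequently reaches the S1 basin before re-entering the
#' closed basin (a commitment check, so fleeting recrossings do not count).
#' Paths without a committed crossing, or never entering the closed basin,
#' are censored with a reason.
#'
#' @param series List of per-path CV series.
#' @param times List of matching time-stamp vectors.
#' @param basins A `basin_bounds` (intervals and barrier on the CV axis).
#' @return Data frame of class `transition_time_set` with columns `path_id`,
#'   `entry_time`, `crossing_time`, `elapsed`, `censored`, `reason`.
#' @export
extract_transition_times <- function(series, times, basins) {
  stopifnot(length(series) == length(times),
            inherits(basins, "basin_bounds"))
  cl <- basins$closed; s1 <- basins$s1; bar <- basins$barrier_position
  rows <- lapply(seq_along(series), function(pid) {
    z <- series[[pid]]; tt <- times[[pid]]
    stopifnot(length(z) == length(tt))
    res <- data.frame(path_id = pid, entry_time = NA_real_,
                      crossing_time = NA_real_, elapsed = NA_real_,
                      censored = TRUE, reason = "")
    entry <- which(z >= cl[1] & z <= cl[2])[1]
    if (is.na(entry)) { res$reason <- "never entered closed basin"; return(res) }
    res$entry_time <- tt[entry]
    i <- entry
    n <- length(z)
    while (i <= n) {
      cross <- which(z[i:n] > bar)[1]
      if (is.na(cross)) { res$reason <- "never crossed barrier"; return(res) }
      cross <- i + cross - 1L
      # committed? reaches S1 before re-entering the closed basin
      j <- cross
      committed <- NA
      while (j <= n) {
        if (z[j] >= s1[1]) { committed <- TRUE; break }
        if (z[j] <= cl[2]) { committed <- FALSE; break }
        j <- j + 1L
      }
      if (isTRUE(committed)) {
        res$crossing_time <- tt[cross]
        res$elapsed <- tt[cross] - tt[entry]
        res$censored <- FALSE
        return(res)
      }
      if (is.na(committed)) { res$reason <- "uncommitted at end of path"
        return(res) }
      i <- j    # recrossed into the closed basin; look for the next attempt
    }
    res$reason <- "never crossed barrier"
    res
  })
  out <- do.call(rbind, rows)
  class(out) <- c("transition_time_set", "data.frame")
  out
}

#' Fit an exponential law to transition times via the empirical CDF
#'
#' Least-squares fit of \eqn{1 - e^{-t/\tau}} to the empirical cumulative
#' distribution function of the uncensored times (the maximum-likelihood
#' estimate, the sample mean, is reported as a cross-check).  Transition
#' events are Poisson, so exponential waiting times are the null shape; a
#' flag marks visibly non-exponential samples (zero variance).
#'
#' @param times Uncensored transition times (>= 3), or a
#'   `transition_time_set`.
#' @return List of class `exponential_fit`: `tau`, `tau_ml`, `method`,
#'   `n`, `degenerate`.
#' @export
fit_exponential <- function(times) {
  if (inherits(times, "transition_time_set"))
    times <- times$elapsed[!times$censored]
  times <- times[is.finite(times)]
  if (length(times) < 3) stop("need at least 3 uncensored transition times")
  ts <- sort(times)
  ecdf_y <- seq_along(ts) / length(ts)
  sse <- function(tau) sum((1 - exp(-ts / tau) - ecdf_y)^2)
  opt <- stats::optimize(sse, c(min(ts) / 100, max(ts) * 100))
  structure(list(tau = opt$minimum, tau_ml = mean(ts),
                 method = "ECDF least squares", n = length(ts),
                 degenerate = stats::sd(ts) == 0),
            class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat("<exponential_fit> tau =", signif(x$tau, 4), "(ECDF LSQ), ",
      signif(x$tau_ml, 4), "(ML) from", x$n, "times\n")
  if (x$degenerate) cat("  warning: degenerate (zero-variance) sample\n")
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test against a fitted exponential
#'
#' Draws a large theoretical sample from Exp(`tau`) with a fixed seed and
#' compares it with the observed times by the two-sample KS test, mirroring
#' the procedure of comparing an empirical CDF with a sampled theoretical
#' one (rather than the one-sample test).
#'
#' @param times Observed transition times.
#' @param tau Fitted mean transition time.
#' @param n_theory Theoretical sample size (>= 1e4).
#' @param seed Seed for the theoretical draw.
#' @return List with `statistic` (D), `p_value`, `n_theory`.
#' @export
ks_two_sample_exponential <- function(times, tau, n_theory = 1e5, seed = 1L) {
  stopifnot(tau > 0, n_theory >= 1e4)
  set.seed(seed)
  theo <- stats::rexp(n_theory, rate = 1 / tau)
  kt <- suppressWarnings(stats::ks.test(times, theo))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       n_theory = n_theory)
}

#' Attempt frequency: upward crossings of a level inside the closed basin
#'
#' Counts upward crossings of `level` that occur while the series is
#' resident in the closed basin (between an entry into the closed interval
#' and the next departure past the barrier), divided by the total residence
#' time.  Sparse frame storage can only miss crossings, so the value is a
#' lower bound at a finite save interval.
#'
#' @param z CV series.
#' @param times Time stamps.
#' @param level Crossing level, between the closed minimum and the barrier.
#' @param basins A `basin_bounds`.
#' @return Crossing frequency in inverse time units, with attributes
#'   `n_crossings` and `residence_time`.
#' @export
crossing_frequency <- function(z, times, level, basins) {
  stopifnot(length(z) == length(times), inherits(basins, "basin_bounds"))
  cl <- basins$closed; bar <- basins$barrier_position
  stopifnot(level > cl[1], level < bar)
  # resident on the closed side: at or below the level (the S1 side lies
  # beyond the barrier, hence above the level, and never counts)
  resident <- z <= level
  dt_steps <- diff(times)
  residence <- sum(dt_steps[resident[-length(resident)]])
  if (residence <= 0) stop("zero residence time in the closed basin")
  up <- z[-1] > level & resident[-length(resident)]
  nu <- sum(up) / residence
  attr(nu, "n_crossings") <- sum(up)
  attr(nu, "residence_time") <- residence
  nu
}

#' Transition-state-theory rate and mean time (Eyring-Polanyi analogue)
#'
#' \eqn{k_{TST} = \nu_c e^{-F^{TS}/(RT)}} with the attempt frequency
#' \eqn{\nu_c} and barrier height \eqn{F^{TS}}; the mean transition time is
#' \eqn{1/k_{TST}}.  With the barrier in kJ/mol and the attempt frequency
#' per nanosecond at 320 K, a 10 kJ/mol barrier and 0.85/ns give about
#' 50 ns.
#'
#' @param f_ts Barrier height in kJ/mol.
#' @param nu_c Attempt frequency (per time unit).
#' @param temperature Temperature in kelvin.
#' @return List with `k_tst` (same inverse time units as `nu_c`) and
#'   `mean_time`.
#' @export
eyring_mean_time <- function(f_ts, nu_c, temperature = 320) {
  stopifnot(nu_c > 0, temperature > 0)
  k <- nu_c * exp(-f_ts / rt_kjmol(temperature))
  list(k_tst = k, mean_time = 1 / k)
}
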