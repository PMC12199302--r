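logistic <- function(eta) 1 / (1 + exp(-eta))

logit <- function(p) log(p / (1 - p))

#' Least-squares logistic fit of committor values
#'
#' Fits \eqn{\hat p(f) = 1/(1 + e^{-(\sum w_k f_k + b)})} to committor
#' probabilities by minimizing \eqn{\sum (\hat p - p)^2} (least squares on
#' the probabilities, not cross-entropy) with Levenberg--Marquardt.
#' Features are expected already scaled; the CV value \eqn{z = \sum w f + b}
#' then places the transition state (\eqn{\hat p = 0.5}) at \eqn{z = 0}.
#'
#' Initialization: weights 0, intercept = logit of the mean committor
#' (clamped away from 0/1).  Non-convergence signals a condition of class
#' `rc_fit_failure` so resampling callers can draw a fresh replicate.
#'
#' @param x Numeric matrix (records x features), scaled.
#' @param p Committor values in [0, 1].
#' @param max_iter Maximum LM iterations.
#' @return List with `weights` (named), `intercept`, `fitted`, `converged`,
#'   `info` (minpack.lm status).
#' @export
logistic_lsq_fit <- function(x, p, max_iter = 200L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(p), all(p >= 0 & p <= 1))
  k <- ncol(x)
  if (nrow(x) < k + 2)
    stop("need at least k + 2 records to fit ", k, " features")
  p0 <- min(max(mean(p), 0.01), 0.99)
  start <- c(logit(p0), numeric(k))
  resid_fn <- function(par) logistic(par[1] + x %*% par[-1]) - p
  jac_fn <- function(par) {
    mu <- as.numeric(logistic(par[1] + x %*% par[-1]))
    cbind(mu * (1 - mu), x * (mu * (1 - mu)))
  }
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn, jac = jac_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter, ftol = 1e-12,
                              ptol = 1e-12))
  converged <- fit$info %in% 1:4
  if (!converged) {
    cond <- structure(class = c("rc_fit_failure", "error", "condition"),
                      list(message = paste0("logistic least-squares fit did ",
                                            "not converge (info = ", fit$info,
                                            ": ", fit$message, ")"),
                           call = sys.call()))
    stop(cond)
  }
  par <- fit$par
  w <- par[-1]
  names(w) <- colnames(x) %||% paste0("f", seq_len(k))
  list(weights = w, intercept = par[1],
       fitted = as.numeric(logistic(par[1] + x %*% w)),
       converged = converged, info = fit$info)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coefficient of determination and adjusted R-squared
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} against the observed mean, and
#' \eqn{R^2_{adj} = 1 - (1 - R^2)(n - 1)/(n - k - 1)} penalizing the number
#' of fitted features `k`.
#'
#' @param observed,predicted Numeric vectors.
#' @param k Number of model features.
#' @return `adjusted_r2` returns a single number; `fit_metrics` returns a
#'   list with `r2`, `adjusted_r2`, `mae`, `mse`, `n`, `k`.
#' @export
adjusted_r2 <- function(observed, predicted, k) {
  n <- length(observed)
  if (n <= k + 1)
    stop("adjusted R-squared needs n > k + 1 (n = ", n, ", k = ", k, ")")
  r2 <- r_squared(observed, predicted)
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

r_squared <- function(observed, predicted) {
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(ifelse(ss_res == 0, 1, -Inf))
  1 - ss_res / ss_tot
}

#' @rdname adjusted_r2
#' @export
fit_metrics <- function(observed, predicted, k) {
  list(r2 = r_squared(observed, predicted),
       adjusted_r2 = adjusted_r2(observed, predicted, k),
       mae = mean(abs(observed - predicted)),
       mse = mean((observed - predicted)^2),
       n = length(observed), k = k)
}
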