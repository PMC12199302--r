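#' Configuration of the Monte-Carlo feature selection
#'
#' @param n_boot Bootstrap training replicates per subset evaluation
#'   (default 20).
#' @param mc_iterations Add/remove proposals per repeat (default 1000).
#' @param n_repeats Independent repeats of the search (default 100).
#' @param retention_fraction Keep features present in at least this fraction
#'   of final subsets (default 0.17).
#' @param p_threshold Bootstrap sign-test p-value above which a coefficient
#'   is pruned after an accepted move (default 0.05).
#' @param temperature Metropolis temperature for the acceptance rule; 0
#'   (default) is strict greedy improvement of the mean adjusted R-squared.
#' @param seed Master seed; per-repeat streams are derived from it.
#' @export
selection_config <- function(n_boot = 20L, mc_iterations = 1000L,
                             n_repeats = 100L, retention_fraction = 0.17,
                             p_threshold = 0.05, temperature = 0, seed = 1L) {
  stopifnot(n_boot >= 2, mc_iterations >= 1, n_repeats >= 1,
            retention_fraction > 0, retention_fraction <= 1,
            p_threshold > 0, temperature >= 0)
  structure(list(n_boot = as.integer(n_boot),
                 mc_iterations = as.integer(mc_iterations),
                 n_repeats = as.integer(n_repeats),
                 retention_fraction = retention_fraction,
                 p_threshold = p_threshold, temperature = temperature,
                 seed = as.integer(seed)),
            class = "selection_config")
}

# fit a subset on one bootstrap replicate, falling back to fresh replicates
# when the fit fails to converge
fit_replicate <- function(xs, p, rows, subset, dataset, pool, seed,
                          max_redraws = 5L) {
  for (try in 0:max_redraws) {
    r <- tryCatch(
      logistic_lsq_fit(xs[rows, subset, drop = FALSE], p[rows]),
      rc_fit_failure = function(e) NULL)
    if (!is.null(r)) return(r)
    rows <- bootstrap_resample(dataset, pool, 1L,
                               seed = derive_seed(seed, 1000L + try))[[1]]
  }
  stop("logistic fit failed on ", max_redraws + 1L, " bootstrap replicates")
}

# mean adjusted R^2 of a subset over bootstrap training replicates,
# evaluated on the validation rows; also returns the per-replicate weights
score_subset <- function(subset, xs, p, reps, val_rows, dataset, pool, seed) {
  k <- length(subset)
  fits <- lapply(seq_along(reps), function(i)
    fit_replicate(xs, p, reps[[i]], subset, dataset, pool,
                  derive_seed(seed, i)))
  scores <- vapply(fits, function(f) {
    pred <- logistic(f$intercept +
                       xs[val_rows, subset, drop = FALSE] %*% f$weights)
    adjusted_r2(p[val_rows], as.numeric(pred), k)
  }, numeric(1))
  w <- do.call(rbind, lapply(fits, `[[`, "weights"))
  colnames(w) <- subset
  list(score = mean(scores), weights = w)
}

boot_sign_p <- function(w_column) {
  2 * min(mean(w_column > 0), mean(w_column < 0))
}

#' Monte-Carlo search for the optimal feature combination
#'
#' Repeated stochastic subset search: starting from a random subset,
#' `mc_iterations` proposals add or remove one random feature (probability
#' 1/2 each); each candidate subset is scored by the mean adjusted
#' R-squared of `n_boot` bootstrap logistic fits evaluated on the validation
#' split, and a proposal is accepted when the score improves (strictly, at
#' the default temperature 0).  After each acceptance, coefficients whose
#' bootstrap sign-test p-value exceeds `p_threshold` are pruned worst-first
#' with rescoring between removals.  Features appearing in at least
#' `retention_fraction` of the `n_repeats` final subsets are selected.
#'
#' @param dataset A `committor_dataset` whose feature matrix holds the
#'   (reduced) candidate features and whose records carry `split` labels
#'   from [stratified_partition()].
#' @param cfg A `selection_config`.
#' @param redraw_validation Redraw the validation split (stratified on the
#'   committor bins) afresh for every repeat (default TRUE); with FALSE the
#'   dataset's fixed `validation` split is used for all repeats.  Redrawing
#'   decouples the retention frequencies from a single validation draw,
#'   which matters for small committor sets.
#' @param validation_frac Fraction of the non-test pool used as validation
#'   when redrawing (default 0.15).
#' @return List with `selected` (feature names), `frequency` (named
#'   fraction of repeats containing each feature), `subsets` (per-repeat
#'   final subsets), `log` (per-repeat data frame of accepted scores).
#' @export
mc_feature_search <- function(dataset, cfg = selection_config(),
                              redraw_validation = TRUE,
                              validation_frac = 0.15) {
  stopifnot(inherits(dataset, "committor_dataset"),
            inherits(cfg, "selection_config"),
            !is.null(dataset$records$split))
  rec <- dataset$records
  nontest <- which(rec$split != "test")
  pool <- which(rec$split == "training")
  val_rows <- which(rec$split == "validation")
  stopifnot(length(pool) >= cfg$n_boot, length(val_rows) >= 3)
  feats <- colnames(dataset$features)
  m <- length(feats)
  # scale once on the training pool and freeze
  mu <- colMeans(dataset$features[pool, , drop = FALSE])
  sd_ <- apply(dataset$features[pool, , drop = FALSE], 2, stats::sd)
  sd_[sd_ == 0] <- 1
  xs <- sweep(sweep(dataset$features, 2, mu), 2, sd_, "/")
  p <- rec$p
  subsets <- vector("list", cfg$n_repeats)
  logs <- vector("list", cfg$n_repeats)
  for (rep_i in seq_len(cfg$n_repeats)) {
    rseed <- derive_seed(cfg$seed, rep_i)
    if (redraw_validation) {
      set.seed(derive_seed(rseed, 11L))
      by_bin <- split(nontest, rec$bin[nontest])
      val_rows <- unlist(lapply(by_bin, function(i)
        resample(i, max(1L, round(validation_frac * length(i))))))
      pool <- setdiff(nontest, val_rows)
    }
    reps <- bootstrap_resample(dataset, pool, cfg$n_boot, seed = rseed)
    set.seed(derive_seed(rseed, 7L))
    cache <- new.env(parent = emptyenv())
    scored <- function(sub) {
      key <- paste(sort(sub), collapse = "|")
      if (!is.null(cache[[key]])) return(cache[[key]])
      s <- score_subset(sort(sub), xs, p, reps, val_rows, dataset, pool, rseed)
      cache[[key]] <- s
      s
    }
    current <- sample(feats, sample.int(min(m, 10L), 1))
    cur <- scored(current)
    log_rows <- list(data.frame(iteration = 0L, k = length(current),
                                adjusted_r2 = cur$score, accepted = TRUE))
    for (it in seq_len(cfg$mc_iterations)) {
      add <- if (length(current) == 0) TRUE
             else if (length(current) == m) FALSE
             else stats::runif(1) < 0.5
      proposal <- if (add) c(current, sample(setdiff(feats, current), 1))
                  else setdiff(current, sample(current, 1))
      if (length(proposal) == 0) next
      prop <- scored(proposal)
      accept <- if (cfg$temperature > 0)
        stats::runif(1) < exp((prop$score - cur$score) / cfg$temperature)
      else prop$score > cur$score
      if (accept) {
        current <- proposal; cur <- prop
        # prune insignificant coefficients, worst first, rescoring between
        repeat {
          if (length(current) <= 1) break
          pv <- apply(cur$weights, 2, boot_sign_p)
          if (all(pv <= cfg$p_threshold)) break
          drop <- names(which.max(pv))
          current <- setdiff(current, drop)
          cur <- scored(current)
        }
        log_rows[[length(log_rows) + 1]] <-
          data.frame(iteration = it, k = length(current),
                     adjusted_r2 = cur$score, accepted = TRUE)
      }
    }
    subsets[[rep_i]] <- sort(current)
    logs[[rep_i]] <- do.call(rbind, log_rows)
  }
  freq <- table(factor(unlist(subsets), levels = feats)) / cfg$n_repeats
  selected <- names(freq)[freq >= cfg$retention_fraction]
  if (length(selected) == 0)
    warning("no feature was retained in at least ",
            sprintf("%.0f%%", 100 * cfg$retention_fraction), " of repeats")
  list(selected = selected, frequency = as.numeric(freq) |>
         stats::setNames(feats), subsets = subsets, log = logs)
}

#' Finalize reaction-coordinate coefficients by bootstrap averaging
#'
#' The selected features are refit on `n_boot` stratified bootstrap
#' replicates of the full training + validation pool; coefficients are
#' averaged, their bootstrap distributions kept for p-values, and the
#' R-squared/MAE/MSE metrics are estimated once per replicate on the
#' held-out test split and averaged.
#'
#' @param dataset A `committor_dataset` with `split` labels whose feature
#'   matrix holds the candidate features.
#' @param selected Character vector of selected feature names.
#' @param n_boot Bootstrap replicates (default 300).
#' @param seed Master seed.
#' @param max_fail_frac Error when more than this fraction of replicate fits
#'   fail (default 0.10).
#' @return An object of class `rc_fit` (see [predict.rc_fit()]).
#' @export
finalize_coefficients <- function(dataset, selected, n_boot = 300L,
                                  seed = 1L, max_fail_frac = 0.10) {
  stopifnot(inherits(dataset, "committor_dataset"), length(selected) >= 1,
            !is.null(dataset$records$split))
  rec <- dataset$records
  pool <- which(rec$split %in% c("training", "validation"))
  test_rows <- which(rec$split == "test")
  mu <- colMeans(dataset$features[pool, selected, drop = FALSE])
  sd_ <- apply(dataset$features[pool, selected, drop = FALSE], 2, stats::sd)
  sd_[sd_ == 0] <- 1
  xs <- sweep(sweep(dataset$features[, selected, drop = FALSE], 2, mu), 2,
              sd_, "/")
  p <- rec$p
  reps <- bootstrap_resample(dataset, pool, n_boot, seed = seed)
  coefs <- matrix(NA_real_, n_boot, length(selected) + 1,
                  dimnames = list(NULL, c("(intercept)", selected)))
  metrics <- matrix(NA_real_, n_boot, 3,
                    dimnames = list(NULL, c("r2", "mae", "mse")))
  failed <- 0L
  for (i in seq_len(n_boot)) {
    f <- tryCatch(logistic_lsq_fit(xs[reps[[i]], , drop = FALSE],
                                   p[reps[[i]]]),
                  rc_fit_failure = function(e) NULL)
    if (is.null(f)) { failed <- failed + 1L; next }
    coefs[i, ] <- c(f$intercept, f$weights)
    if (length(test_rows) > 0) {
      pred <- as.numeric(logistic(f$intercept +
                                    xs[test_rows, , drop = FALSE] %*%
                                    f$weights))
      metrics[i, ] <- c(r_squared(p[test_rows], pred),
                        mean(abs(p[test_rows] - pred)),
                        mean((p[test_rows] - pred)^2))
    }
  }
  if (failed > max_fail_frac * n_boot)
    stop(failed, " of ", n_boot, " bootstrap fits failed (> ",
         sprintf("%.0f%%", 100 * max_fail_frac), ")")
  ok <- !is.na(coefs[, 1])
  cm <- colMeans(coefs[ok, , drop = FALSE])
  pvals <- apply(coefs[ok, -1, drop = FALSE], 2, boot_sign_p)
  z <- as.numeric(cm[1] + xs %*% cm[-1])
  object <- structure(
    list(features = selected, weights = cm[-1], intercept = cm[1],
         scale_mean = mu, scale_sd = sd_,
         boot_coefficients = coefs[ok, , drop = FALSE],
         p_values = pvals,
         metrics = as.list(colMeans(metrics[ok, , drop = FALSE],
                                    na.rm = TRUE)),
         metrics_sd = as.list(apply(metrics[ok, , drop = FALSE], 2,
                                    stats::sd, na.rm = TRUE)),
         n_boot = n_boot, n_failed = failed, seed = seed,
         data = list(p = p, z = z, split = rec$split),
         call = sys.call()),
    class = "rc_fit")
  object
}

#' Predict committor probabilities or CV values from an optimized RC
#'
#' @param object An `rc_fit`.
#' @param newdata Matrix (or `feature_matrix`) holding the model's features
#'   in raw (unscaled) units; omit to use the fitting data.
#' @param type `"committor"` for \eqn{\hat p}, `"cv"` for the linear CV
#'   value \eqn{z} (transition state at \eqn{z = 0}).
#' @param ... Unused.
#' @export
predict.rc_fit <- function(object, newdata = NULL,
                           type = c("committor", "cv"), ...) {
  type <- match.arg(type)
  z <- if (is.null(newdata)) object$data$z else {
    vals <- if (inherits(newdata, "feature_matrix")) newdata$values
            else as.matrix(newdata)
    idx <- match(object$features, colnames(vals))
    if (anyNA(idx))
      stop("newdata lacks feature(s): ",
           paste(object$features[is.na(idx)], collapse = ", "))
    xs <- sweep(sweep(vals[, idx, drop = FALSE], 2, object$scale_mean), 2,
                object$scale_sd, "/")
    as.numeric(object$intercept + xs %*% object$weights)
  }
  if (type == "cv") z else as.numeric(logistic(z))
}

#' @export
coef.rc_fit <- function(object, ...) {
  stats::setNames(c(object$intercept, object$weights),
                  c("(intercept)", object$features))
}

#' @export
residuals.rc_fit <- function(object, ...) {
  object$data$p - logistic(object$data$z)
}

#' @export
fitted.rc_fit <- function(object, ...) logistic(object$data$z)

#' @export
print.rc_fit <- function(x, ...) {
  cat("Optimized reaction coordinate (logistic committor model)\n")
  cat("  features:", length(x$features), " bootstrap replicates:",
      nrow(x$boot_coefficients), "\n")
  cat("  test-set R2 =", signif(x$metrics$r2, 3),
      " MAE =", signif(x$metrics$mae, 3),
      " MSE =", signif(x$metrics$mse, 3), "\n")
  invisible(x)
}

#' @export
summary.rc_fit <- function(object, ...) {
  se <- apply(object$boot_coefficients, 2, stats::sd)
  tab <- data.frame(estimate = c(object$intercept, object$weights),
                    boot_se = se,
                    p_value = c(NA, object$p_values))
  rownames(tab) <- c("(intercept)", object$features)
  out <- list(coefficients = tab, metrics = object$metrics,
              metrics_sd = object$metrics_sd, n_boot = object$n_boot,
              n_failed = object$n_failed)
  class(out) <- "summary.rc_fit"
  out
}

#' @export
print.summary.rc_fit <- function(x, ...) {
  cat("Optimized reaction coordinate - bootstrap summary\n\n")
  print(round(x$coefficients, 4))
  cat("\nTest-set metrics (bootstrap means): R2 =", signif(x$metrics$r2, 3),
      " MAE =", signif(x$metrics$mae, 3),
      " MSE =", signif(x$metrics$mse, 3), "\n")
  if (x$n_failed > 0) cat(x$n_failed, "replicate fit(s) failed\n")
  invisible(x)
}

#' @export
plot.rc_fit <- function(x, ...) {
  graphics::plot(logistic(x$data$z), x$data$p,
                 xlab = "predicted committor", ylab = "observed committor",
                 pch = 19, cex = 0.6,
                 col = ifelse(x$data$split == "test", "firebrick", "grey40"),
                 ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate shooting outcomes from a fitted committor model
#'
#' Draws binomial committor estimates at the fitted probabilities,
#' emulating `n_shots`-shot shooting at each record.
#'
#' @param object An `rc_fit`.
#' @param nsim Number of simulated datasets.
#' @param seed Optional seed.
#' @param n_shots Shots per record (default 100).
#' @param ... Unused.
#' @return Data frame (nsim = 1) or list of data frames with column `p_sim`.
#' @export
simulate.rc_fit <- function(object, nsim = 1, seed = NULL, n_shots = 100,
                            ...) {
  if (!is.null(seed)) set.seed(seed)
  ph <- logistic(object$data$z)
  out <- lapply(seq_len(nsim), function(i)
    data.frame(p_sim = stats::rbinom(length(ph), n_shots, ph) / n_shots))
  if (nsim == 1) out[[1]] else out
}

#' Express an optimized RC as a single linear CV over original features
#'
#' Composes the fitted weights with the reduced-feature linear maps so the
#' optimized coordinate can be exported (e.g. for biasing in an external
#' engine) as one linear combination of the original features.
#'
#' @param object An `rc_fit` fitted on the `series` of `reduced`.
#' @param reduced The `reduced_feature_set` behind the fit.
#' @return A `linear_cv`.
#' @export
rc_as_linear_cv <- function(object, reduced) {
  stopifnot(inherits(object, "rc_fit"), inherits(reduced, "reduced_feature_set"))
  rnames <- vapply(reduced$maps, function(m) m$provenance$reduced %||% "",
                   character(1))
  feats <- character(); w <- numeric(); mu <- numeric(); sd_ <- numeric()
  b <- object$intercept
  for (j in seq_along(object$features)) {
    map <- reduced$maps[[match(object$features[j], rnames)]]
    cj <- object$weights[j] / object$scale_sd[j]
    for (k in seq_along(map$features)) {
      f <- map$features[k]
      pos <- match(f, feats)
      if (is.na(pos)) {
        feats <- c(feats, f); w <- c(w, cj * map$weights[k])
        mu <- c(mu, map$scale_mean[k]); sd_ <- c(sd_, map$scale_sd[k])
      } else w[pos] <- w[pos] + cj * map$weights[k]
    }
    b <- b + cj * (map$intercept - object$scale_mean[j])
  }
  linear_cv(feats, mu, sd_, w, b,
            provenance = list(stage = "optimized_rc",
                              reduced_features = object$features,
                              weights = as.numeric(object$weights),
                              seed = object$seed))
}

#' Transition-state diagnostics of an optimized reaction coordinate
#'
#' Restricts the records to the CV stripe around the transition state
#' (default \eqn{z \in [-0.25, 0.25]}) and summarizes their committor
#' histogram (a good coordinate shows a distinct peak near 0.5), plus
#' sign-consistency rates over all records: the fraction of `z > 0` records
#' with `p > 0.5` and of `z < 0` records with `p < 0.5`.
#'
#' @param p Observed committor values.
#' @param z CV values aligned with `p`.
#' @param stripe Stripe bounds on `z` (default `c(-0.25, 0.25)`).
#' @param breaks Histogram breaks on the committor axis.
#' @return List with `histogram`, `peak_bin_mid`, `mean_committor`,
#'   `n_stripe`, `sign_consistency_s1`, `sign_consistency_closed`.
#' @export
ts_diagnostics <- function(p, z, stripe = c(-0.25, 0.25),
                           breaks = seq(0, 1, 0.1)) {
  stopifnot(length(p) == length(z), stripe[1] < stripe[2])
  in_stripe <- z >= stripe[1] & z <= stripe[2]
  if (!any(in_stripe)) stop("no records fall inside the stripe")
  h <- graphics::hist(p[in_stripe], breaks = breaks, plot = FALSE)
  list(histogram = h,
       peak_bin_mid = h$mids[which.max(h$counts)],
       mean_committor = mean(p[in_stripe]),
       n_stripe = sum(in_stripe),
       sign_consistency_s1 = mean(p[z > 0] > 0.5),
       sign_consistency_closed = mean(p[z < 0] < 0.5))
}

#' Split an optimized CV into two interpretable parts
#'
#' Clusters the final features at a coarse resolution, assigns each cluster
#' to one of two groups, and assembles two sub-variables that reuse the full
#' CV's coefficients (so the parts sum to the full CV up to the intercept,
#' which goes to the part with the larger weight norm by default).
#'
#' @param object An `rc_fit`.
#' @param series Records x feature matrix of the model's features (raw
#'   units) used to compute cluster structure and the inter-part
#'   correlation.
#' @param gamma Leiden resolution (default 0.2).
#' @param grouping Optional named integer vector mapping cluster ids to part
#'   1 or 2; every cluster must be assigned.  When `NULL`, clusters are
#'   assigned greedily to balance the weight norms.
#' @param seed Clustering seed.
#' @return List of class `split_cv` with `part1`, `part2` (feature names,
#'   weights, intercepts), `clusters`, `series` values of both parts and
#'   their Pearson correlation `r`.
#' @export
split_cv <- function(object, series, gamma = 0.2, grouping = NULL,
                     seed = 1L) {
  stopifnot(inherits(object, "rc_fit"))
  series <- as.matrix(series)[, object$features, drop = FALSE]
  cl <- correlation_cluster(series, gamma = gamma, seed = seed)
  ids <- sort(unique(cl))
  if (is.null(grouping)) {
    norms <- vapply(ids, function(i)
      sqrt(sum(object$weights[names(cl)[cl == i]]^2)), numeric(1))
    ord <- order(norms, decreasing = TRUE)
    grouping <- integer(length(ids)); names(grouping) <- as.character(ids)
    tot <- c(0, 0)
    for (i in ord) {
      g <- which.min(tot)
      grouping[as.character(ids[i])] <- g
      tot[g] <- tot[g] + norms[i]
    }
  }
  if (!all(as.character(ids) %in% names(grouping)))
    stop("grouping leaves cluster(s) unassigned: ",
         paste(setdiff(as.character(ids), names(grouping)), collapse = ", "))
  part_feats <- lapply(1:2, function(g)
    names(cl)[cl %in% ids[grouping[as.character(ids)] == g]])
  if (any(lengths(part_feats) == 0))
    warning("one part is empty; its series is constant 0 and the ",
            "inter-part correlation is undefined")
  part_of <- function(feats, take_intercept) {
    idx <- match(feats, object$features)
    list(features = feats, weights = object$weights[idx],
         scale_mean = object$scale_mean[idx], scale_sd = object$scale_sd[idx],
         intercept = if (take_intercept) object$intercept else 0)
  }
  norm1 <- sqrt(sum(object$weights[part_feats[[1]]]^2))
  norm2 <- sqrt(sum(object$weights[part_feats[[2]]]^2))
  p1 <- part_of(part_feats[[1]], norm1 >= norm2)
  p2 <- part_of(part_feats[[2]], norm1 < norm2)
  eval_part <- function(p) {
    if (length(p$features) == 0) return(rep(0, nrow(series)))
    xs <- sweep(sweep(series[, p$features, drop = FALSE], 2, p$scale_mean),
                2, p$scale_sd, "/")
    as.numeric(xs %*% p$weights + p$intercept)
  }
  s1 <- eval_part(p1); s2 <- eval_part(p2)
  r <- if (stats::sd(s1) > 0 && stats::sd(s2) > 0) stats::cor(s1, s2)
       else NA_real_
  structure(list(part1 = p1, part2 = p2, clusters = cl, grouping = grouping,
                 series1 = s1, series2 = s2, r = r),
            class = "split_cv")
}

#' @export
print.split_cv <- function(x, ...) {
  cat("<split_cv> part1:", length(x$part1$features), "features; part2:",
      length(x$part2$features), "features; inter-part r =",
      signif(x$r, 3), "\n")
  invisible(x)
}
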