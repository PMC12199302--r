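#' Linear collective variable
#'
#' A collective variable of the form
#' \eqn{z = \sum_k w_k (f_k - \mu_k)/\sigma_k + b} over named features, with
#' the scaling statistics frozen into the object so evaluation is invariant
#' to how raw features were stored.
#'
#' @param features Character vector of feature names.
#' @param scale_mean,scale_sd Per-feature scaling statistics.
#' @param weights Per-feature weights (finite).
#' @param intercept Intercept b.
#' @param provenance Named list describing how the CV was built.
#' @return Object of class `linear_cv`.
#' @export
linear_cv <- function(features, scale_mean, scale_sd, weights, intercept = 0,
                      provenance = list()) {
  stopifnot(length(features) == length(weights),
            length(scale_mean) == length(features),
            length(scale_sd) == length(features),
            all(is.finite(weights)), all(scale_sd > 0))
  structure(list(features = features, scale_mean = as.numeric(scale_mean),
                 scale_sd = as.numeric(scale_sd),
                 weights = as.numeric(weights),
                 intercept = as.numeric(intercept), provenance = provenance),
            class = "linear_cv")
}

#' @export
print.linear_cv <- function(x, ...) {
  cat("<linear_cv> over", length(x$features), "features; |w| =",
      signif(sqrt(sum(x$weights^2)), 4), "; intercept =",
      signif(x$intercept, 4), "\n")
  invisible(x)
}

#' @export
coef.linear_cv <- function(object, ...) {
  stats::setNames(c(object$weights, object$intercept),
                  c(object$features, "(intercept)"))
}

#' Evaluate a linear CV on new data
#'
#' @param object A `linear_cv`.
#' @param newdata A `feature_matrix` or a numeric matrix with named columns
#'   covering the CV's features (raw, unscaled values).
#' @param ... Unused.
#' @return Numeric CV values, one per row.
#' @export
predict.linear_cv <- function(object, newdata, ...) {
  vals <- if (inherits(newdata, "feature_matrix")) newdata$values else
    as.matrix(newdata)
  idx <- match(object$features, colnames(vals))
  if (anyNA(idx))
    stop("newdata is missing feature(s): ",
         paste(object$features[is.na(idx)], collapse = ", "))
  z <- sweep(sweep(vals[, idx, drop = FALSE], 2, object$scale_mean), 2,
             object$scale_sd, "/")
  as.numeric(z %*% object$weights + object$intercept)
}

#' Serialize / restore a linear CV as JSON
#' @param cv A `linear_cv`.
#' @param path File path.
#' @export
write_cv_json <- function(cv, path) {
  jsonlite::write_json(unclass(cv), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cv_json
#' @export
read_cv_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  linear_cv(x$features, x$scale_mean, x$scale_sd, x$weights, x$intercept,
            as.list(x$provenance))
}

#' PCA reduction of a feature matrix
#'
#' Z-scores the pooled features and projects onto the leading principal
#' components, reporting the cumulative variance share retained (the
#' convention is to keep enough components to describe the transition while
#' discarding movements unrelated to it; the contacts CV keeps 2 components,
#' the distances CV 5, by default downstream).
#'
#' @param fm A pooled `feature_matrix`.
#' @param n_components Number of components, `1 <= n_components <= rank`.
#' @return Object of class `pca_reduction`: `projections`, `var_share`
#'   (per-component), `cum_var_share`, `loadings`, `features`,
#'   `scale_mean`, `scale_sd`.
#' @export
pca_reduce <- function(fm, n_components) {
  stopifnot(inherits(fm, "feature_matrix"), n_components >= 1,
            n_components <= ncol(fm$values))
  z <- scale(fm$values)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-10)
  if (n_components > rank)
    stop("n_components (", n_components, ") exceeds data rank (", rank, ")")
  shares <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(projections = pc$x[, seq_len(n_components), drop = FALSE],
                 var_share = shares[seq_len(n_components)],
                 cum_var_share = sum(shares[seq_len(n_components)]),
                 loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
                 features = colnames(fm$values),
                 scale_mean = attr(z, "scaled:center"),
                 scale_sd = attr(z, "scaled:scale"),
                 path_id = attr(fm, "path_id")),
            class = "pca_reduction")
}

#' Label terminal frames of reactive paths for CV training
#'
#' Marks the first `frac` of each path's frames as `"closed"` and the last
#' `frac` as `"S1"`; everything else is `NA` (unused by the classifier).
#'
#' @param path_id Integer vector mapping pooled frames to paths.
#' @param frac Terminal window fraction (default 0.10).
#' @return Character vector of labels aligned with the pooled frames.
#' @export
label_terminal_frames <- function(path_id, frac = 0.10) {
  stopifnot(frac > 0, frac <= 0.5)
  lab <- rep(NA_character_, length(path_id))
  for (p in unique(path_id)) {
    i <- which(path_id == p)
    k <- max(1L, floor(frac * length(i)))
    lab[i[seq_len(k)]] <- "closed"
    lab[i[(length(i) - k + 1):length(i)]] <- "S1"
  }
  lab
}

#' Fit a max-margin linear collective variable
#'
#' Trains a soft-margin linear SVM (C = 1, class-balanced weights) on the PC
#' projections of labelled frames and composes the separating direction with
#' the PCA loadings and feature scaling into a single `linear_cv` over the
#' original features.  Sign convention: the S1 side is positive.
#'
#' @param reduction A `pca_reduction`.
#' @param labels Character labels per pooled frame (`"closed"`/`"S1"`, `NA`
#'   for unlabelled frames), as from [label_terminal_frames()].
#' @return A `linear_cv` with attribute `training_accuracy`.
#' @export
fit_svm_cv <- function(reduction, labels) {
  stopifnot(inherits(reduction, "pca_reduction"),
            length(labels) == nrow(reduction$projections))
  keep <- !is.na(labels)
  y <- factor(labels[keep], levels = c("closed", "S1"))
  if (nlevels(droplevels(y)) < 2)
    stop("labels must contain both classes")
  x <- reduction$projections[keep, , drop = FALSE]
  wts <- 1 / table(y); wts <- wts / sum(wts) * 2
  fit <- e1071::svm(x, y, kernel = "linear", cost = 1, scale = FALSE,
                    class.weights = stats::setNames(as.numeric(wts),
                                                    names(wts)))
  w_pc <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # e1071 decision values are positive for the first level; flip so S1 > 0
  dv <- x %*% w_pc + b
  if (mean(dv[y == "S1"]) < mean(dv[y == "closed"])) {
    w_pc <- -w_pc; b <- -b; dv <- -dv
  }
  acc <- mean((dv > 0) == (y == "S1"))
  w_feat <- as.numeric(reduction$loadings %*% w_pc)
  cv <- linear_cv(reduction$features, reduction$scale_mean,
                  reduction$scale_sd, w_feat, b,
                  provenance = list(stage = "svm_cv",
                                    n_components = ncol(reduction$projections),
                                    cum_var_share = reduction$cum_var_share,
                                    cost = 1))
  attr(cv, "training_accuracy") <- acc
  cv
}
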