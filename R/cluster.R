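#' Filter features by correlation with the committor
#'
#' Keeps features whose absolute Pearson correlation with the committor
#' values exceeds `threshold` (default 0.1); constant features are dropped
#' with a warning.
#'
#' @param x Records x features matrix (named columns).
#' @param p Committor values aligned with the rows.
#' @param threshold Absolute-correlation threshold.
#' @return The filtered matrix with attribute `committor_r`.
#' @export
committor_corr_filter <- function(x, p, threshold = 0.1) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(p))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    warning("dropping constant feature(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
  r <- rep(NA_real_, ncol(x))
  r[sds > 0] <- as.numeric(stats::cor(x[, sds > 0, drop = FALSE], p))
  keep <- !is.na(r) & abs(r) > threshold
  out <- x[, keep, drop = FALSE]
  attr(out, "committor_r") <- r[keep]
  out
}

#' Correlation clustering of features by Leiden community detection
#'
#' Builds the complete feature graph weighted by absolute Pearson
#' correlation and partitions it with the Leiden algorithm under the
#' constant-Potts-model objective at resolution `gamma` (the MoSAIC-style
#' correlation clustering: blocks of mutually correlated features become
#' communities, independent features become singletons as `gamma` grows).
#'
#' @param x Records x features matrix (>= 2 features), or a correlation
#'   matrix passed via `cor_mat`.
#' @param gamma Resolution parameter (> 0).
#' @param seed RNG seed (the partition is deterministic given the seed).
#' @param cor_mat Optional precomputed correlation matrix.
#' @return Integer cluster assignment named by feature.
#' @export
correlation_cluster <- function(x, gamma = 0.6, seed = 1L, cor_mat = NULL) {
  stopifnot(gamma > 0)
  if (is.null(cor_mat)) {
    x <- as.matrix(x)
    if (ncol(x) == 1)
      return(stats::setNames(1L, colnames(x)))
    cor_mat <- abs(stats::cor(x))
  }
  cor_mat[is.na(cor_mat)] <- 0
  diag(cor_mat) <- 0
  g <- igraph::graph_from_adjacency_matrix(cor_mat, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "CPM",
                               resolution = gamma, n_iterations = 5)
  stats::setNames(as.integer(igraph::membership(cl)), colnames(cor_mat))
}

#' Reduce feature clusters to their first principal components
#'
#' Z-scores each cluster's members and keeps the PC1 series as one reduced
#' feature (sign fixed to correlate positively with the member mean); a
#' warning is raised when PC1 explains less than `min_var_share` of a
#' cluster's variance.  A second round then merges any reduced features
#' whose pairwise absolute correlation exceeds `merge_threshold`, using the
#' same PCA construction, so the final set is pairwise decorrelated below
#' that threshold.  Every reduced feature is stored as a [linear_cv()] over
#' the original features, so the reduction can be applied to new data.
#'
#' @param x Records x features matrix (named columns).
#' @param clusters Integer assignment covering all columns of `x`
#'   (as from [correlation_cluster()]).
#' @param min_var_share PC1 variance-share warning threshold (default 0.70).
#' @param merge_threshold Second-round merge threshold on |r| (default 0.7).
#' @return Object of class `reduced_feature_set`: list with `series`
#'   (records x reduced matrix), `maps` (list of `linear_cv`), `provenance`
#'   data frame (members, PC1 variance share, merge round).
#' @export
cluster_pc1_reduce <- function(x, clusters, min_var_share = 0.70,
                               merge_threshold = 0.7) {
  x <- as.matrix(x)
  stopifnot(length(clusters) == ncol(x))
  reduce_once <- function(mat, assign, base_maps = NULL) {
    ids <- sort(unique(assign))
    maps <- list(); series <- list(); prov <- list()
    for (cid in ids) {
      members <- which(assign == cid)
      sub <- mat[, members, drop = FALSE]
      if (length(members) == 1) {
        # singleton: pass through unchanged (identity map on the raw value)
        nm <- colnames(mat)[members]
        maps[[length(maps) + 1]] <-
          compose_identity(nm, base_maps)
        series[[length(series) + 1]] <- sub[, 1]
        prov[[length(prov) + 1]] <- data.frame(
          reduced = NA_character_, members = nm, var_share = 1)
        next
      }
      m <- colMeans(sub); s <- apply(sub, 2, stats::sd); s[s == 0] <- 1
      z <- sweep(sweep(sub, 2, m), 2, s, "/")
      pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
      load <- pc$rotation[, 1]
      proj <- as.numeric(z %*% load)
      if (stats::cor(proj, rowMeans(z)) < 0) { load <- -load; proj <- -proj }
      vs <- pc$sdev[1]^2 / sum(pc$sdev^2)
      if (vs < min_var_share)
        warning("cluster ", cid, ": PC1 explains only ",
                sprintf("%.0f%%", 100 * vs), " of the variance")
      maps[[length(maps) + 1]] <-
        compose_pca_map(colnames(mat)[members], m, s, load, base_maps)
      series[[length(series) + 1]] <- proj
      prov[[length(prov) + 1]] <- data.frame(
        reduced = NA_character_,
        members = paste(colnames(mat)[members], collapse = ","),
        var_share = vs)
    }
    series <- do.call(cbind, series)
    colnames(series) <- sprintf("rf%03d", seq_len(ncol(series)))
    prov <- do.call(rbind, prov)
    prov$reduced <- colnames(series)
    for (i in seq_along(maps)) maps[[i]]$provenance$reduced <- colnames(series)[i]
    list(series = series, maps = maps, prov = prov)
  }
  r1 <- reduce_once(x, clusters)
  # round two: merge reduced features still correlated above the threshold
  if (ncol(r1$series) > 1) {
    cm <- abs(stats::cor(r1$series))
    diag(cm) <- 0
    if (any(cm > merge_threshold)) {
      g <- igraph::graph_from_adjacency_matrix(cm > merge_threshold,
                                               mode = "undirected")
      comp <- igraph::components(g)$membership
      r2 <- reduce_once(r1$series, as.integer(comp), base_maps = r1$maps)
      r1 <- r2
    }
  }
  r1$prov$round <- 1L
  structure(list(series = r1$series, maps = r1$maps, provenance = r1$prov),
            class = "reduced_feature_set")
}

# identity "map" for singleton clusters: weight 1, no scaling
compose_identity <- function(name, base_maps) {
  if (!is.null(base_maps)) {
    pos <- match(name, vapply(base_maps, function(m)
      m$provenance$reduced %||% "", character(1)))
    if (!is.na(pos)) return(base_maps[[pos]])
  }
  linear_cv(name, 0, 1, 1, 0, provenance = list(stage = "cluster_pc1",
                                                singleton = TRUE))
}

# compose a z-score + PC1 projection with optional underlying linear maps
compose_pca_map <- function(members, m, s, load, base_maps) {
  if (is.null(base_maps)) {
    return(linear_cv(members, m, s, load, 0,
                     provenance = list(stage = "cluster_pc1",
                                       members = members,
                                       loadings = as.numeric(load))))
  }
  # members are reduced features of round 1: expand to original features
  idx <- match(members, vapply(base_maps, function(mp)
    mp$provenance$reduced %||% "", character(1)))
  feats <- character(); w <- numeric(); mu <- numeric(); sd_ <- numeric()
  b <- 0
  for (r in seq_along(idx)) {
    base <- base_maps[[idx[r]]]
    coefr <- load[r] / s[r]
    # coefr * ((base(f) - m_r)) where base(f) = sum w_b z(f) + b_b
    for (k in seq_along(base$features)) {
      f <- base$features[k]
      pos <- match(f, feats)
      if (is.na(pos)) {
        feats <- c(feats, f); w <- c(w, coefr * base$weights[k])
        mu <- c(mu, base$scale_mean[k]); sd_ <- c(sd_, base$scale_sd[k])
      } else {
        w[pos] <- w[pos] + coefr * base$weights[k]
      }
    }
    b <- b + coefr * (base$intercept - m[r])
  }
  linear_cv(feats, mu, sd_, w, b,
            provenance = list(stage = "cluster_pc1_merged",
                              members = members,
                              loadings = as.numeric(load)))
}

#' Apply a reduced feature set to new raw feature data
#'
#' @param reduced A `reduced_feature_set`.
#' @param newdata Matrix or `feature_matrix` of original features.
#' @return Records x reduced-features matrix.
#' @export
reduce_transform <- function(reduced, newdata) {
  stopifnot(inherits(reduced, "reduced_feature_set"))
  out <- vapply(reduced$maps, function(m) predict(m, newdata),
                numeric(if (inherits(newdata, "feature_matrix"))
                  nrow(newdata$values) else nrow(as.matrix(newdata))))
  out <- as.matrix(out)
  colnames(out) <- colnames(reduced$series)
  out
}

#' @export
print.reduced_feature_set <- function(x, ...) {
  cat("<reduced_feature_set>", ncol(x$series), "reduced features from",
      sum(lengths(lapply(x$maps, `[[`, "features"))), "original features\n")
  invisible(x)
}
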