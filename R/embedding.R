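#' Specification of the synthetic feature embedding
#'
#' Describes how a latent transition coordinate is dressed up as a
#' high-dimensional feature table with the statistical structure of real
#' contact/coordination/distance series: informative features are monotone
#' functions (links) of the transition coordinate plus noise, decoys are
#' independent of it, and collinear blocks of decoys share a latent factor.
#' Ground-truth roles are stored in the resulting feature metadata so that
#' selection methods can be scored against the plant.
#'
#' @param n_informative Number of informative features.
#' @param n_decoy Total number of decoy features (collinear blocks consume
#'   decoy slots first; the rest are mutually independent).
#' @param collinear_blocks List of `c(size, correlation_target)` pairs;
#'   correlation targets in (0, 1].
#' @param link Character vector recycled over informative features:
#'   `"linear"` or `"sigmoid"` (saturating) monotone maps.
#' @param noise_sd Additive Gaussian noise standard deviation (recycled per
#'   feature).
#' @param decoy_ar AR(1) coefficient of decoy latent factors in [0, 1);
#'   0 (default) gives white decoys.
#' @param seed Seed controlling the realized link parameters (shared across
#'   all paths embedded with this spec).
#' @return A `feature_embedding_spec`.
#' @export
feature_embedding_spec <- function(n_informative = 5, n_decoy = 55,
                                   collinear_blocks = list(c(5, 0.9), c(5, 0.9)),
                                   link = c("sigmoid", "sigmoid", "sigmoid",
                                            "sigmoid", "linear"),
                                   noise_sd = 0.3, decoy_ar = 0, seed = 1L) {
  stopifnot(n_informative >= 0, n_decoy >= 0, all(noise_sd >= 0),
            decoy_ar >= 0, decoy_ar < 1,
            all(link %in% c("linear", "sigmoid")))
  blocks <- lapply(collinear_blocks, function(b) {
    stopifnot(length(b) == 2, b[1] >= 2, b[2] > 0, b[2] <= 1)
    list(size = as.integer(b[1]), rho = as.numeric(b[2]))
  })
  if (sum(vapply(blocks, `[[`, integer(1), "size")) > n_decoy)
    stop("collinear blocks require more decoy slots than n_decoy provides")
  structure(list(n_informative = as.integer(n_informative),
                 n_decoy = as.integer(n_decoy), blocks = blocks,
                 link = link, noise_sd = noise_sd, decoy_ar = decoy_ar,
                 seed = as.integer(seed)),
            class = "feature_embedding_spec")
}

# Draw the deterministic per-feature link parameters implied by the spec
# seed.  Amplitudes are normalized so each link spans ~2 units across the
# reference wells at -1/+1, keeping features commensurate before scaling.
realize_embedding <- function(spec) {
  stopifnot(inherits(spec, "feature_embedding_spec"))
  n <- spec$n_informative
  if (n == 0) return(list(spec = spec, links = list()))
  old <- .Random.seed_safe()
  set.seed(spec$seed)
  types <- rep_len(spec$link, n)
  # sigmoid midpoints are spread across the transition region so different
  # informative features saturate at different stages (complementary
  # reporters, the way distinct contacts break at distinct points)
  n_sig <- sum(types == "sigmoid")
  centers <- if (n_sig > 0)
    seq(-0.6, 0.6, length.out = max(n_sig, 2))[seq_len(n_sig)] +
      stats::runif(n_sig, -0.08, 0.08)
  sig_i <- 0L
  links <- lapply(seq_len(n), function(k) {
    sign <- sample(c(-1, 1), 1)
    if (types[k] == "linear") {
      list(type = "linear", a = sign * stats::runif(1, 0.7, 1.3), b = 0)
    } else {
      sig_i <<- sig_i + 1L
      list(type = "sigmoid", s = stats::runif(1, 3, 6),
           c = centers[sig_i], amp = sign * 2)
    }
  })
  .Random.seed_restore(old)
  links
}

link_value <- function(lk, x) {
  switch(lk$type,
         linear = lk$a * x + lk$b,
         sigmoid = lk$amp / (1 + exp(-lk$s * (x - lk$c))))
}

link_deriv <- function(lk, x) {
  switch(lk$type,
         linear = rep(lk$a, length(x)),
         sigmoid = {
           e <- exp(-lk$s * (x - lk$c))
           lk$amp * lk$s * e / (1 + e)^2
         })
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
                                                       envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Embed a latent trajectory into a synthetic feature table
#'
#' @param traj A `latent_trajectory`.
#' @param spec A `feature_embedding_spec`.
#' @param noise_seed Seed for the per-frame noise and decoy factors; use a
#'   different value per path while keeping `spec` (and hence the link
#'   parameters) fixed.
#' @return A `feature_matrix` whose metadata records ground truth: `role`
#'   (informative/decoy), `block` (0 = none), `link` type and `kind`
#'   (synthetic-contact / synthetic-distance, alternating so two feature
#'   families exist downstream).
#' @export
embed_features <- function(traj, spec, noise_seed = spec$seed) {
  stopifnot(inherits(traj, "latent_trajectory"),
            inherits(spec, "feature_embedding_spec"))
  x <- traj$coords[, 1]
  nf <- nrow(traj$coords)
  links <- realize_embedding(spec)
  set.seed(noise_seed)
  n_tot <- spec$n_informative + spec$n_decoy
  sds <- rep_len(spec$noise_sd, n_tot)
  vals <- matrix(NA_real_, nf, n_tot)
  role <- character(n_tot); block <- integer(n_tot); ltype <- character(n_tot)
  j <- 0L
  for (k in seq_len(spec$n_informative)) {
    j <- j + 1L
    vals[, j] <- link_value(links[[k]], x) + stats::rnorm(nf, sd = sds[j])
    role[j] <- "informative"; block[j] <- 0L; ltype[j] <- links[[k]]$type
  }
  ar_series <- function(n, phi) {
    if (phi == 0) return(stats::rnorm(n))
    as.numeric(stats::arima.sim(list(ar = phi), n)) * sqrt(1 - phi^2)
  }
  bid <- 0L
  for (b in spec$blocks) {
    bid <- bid + 1L
    z <- ar_series(nf, spec$decoy_ar)
    for (i in seq_len(b$size)) {
      # within-block noise is the sqrt(1 - rho) term itself, so the pairwise
      # correlation hits the stated target exactly in expectation
      j <- j + 1L
      vals[, j] <- sqrt(b$rho) * z + sqrt(1 - b$rho) * stats::rnorm(nf)
      role[j] <- "decoy"; block[j] <- bid; ltype[j] <- "none"
    }
  }
  while (j < n_tot) {
    j <- j + 1L
    vals[, j] <- ar_series(nf, spec$decoy_ar)
    role[j] <- "decoy"; block[j] <- 0L; ltype[j] <- "none"
  }
  kind <- ifelse(seq_len(n_tot) %% 2 == 1, "synthetic-contact",
                 "synthetic-distance")
  # collinear blocks play the role of redundant distance features (adjacent
  # helical-turn distances co-vary); keeping them out of the contact family
  # preserves the contact-PCA transition template
  kind[block > 0] <- "synthetic-distance"
  name <- sprintf("%s%03d", ifelse(role == "informative", "inf", "dcy"),
                  seq_len(n_tot))
  meta <- data.frame(name = name, kind = kind, role = role, block = block,
                     link = ltype, stringsAsFactors = FALSE)
  colnames(vals) <- name
  feature_matrix(traj$times, vals, meta)
}

#' Deterministic mean map of an embedding and its gradient
#'
#' Returns, for a chosen set of features, functions giving the noise-free
#' feature values and their derivative with respect to the latent transition
#' coordinate.  Decoy features have constant mean 0 and zero derivative.
#' Used to apply bias forces through a linear CV by the chain rule.
#'
#' @param spec A `feature_embedding_spec`.
#' @param features Character vector of feature names (defaults to all).
#' @return List with `value(x)` and `deriv(x)` returning matrices
#'   length(x) x length(features).
#' @export
embedding_mean_map <- function(spec, features = NULL) {
  links <- realize_embedding(spec)
  n_tot <- spec$n_informative + spec$n_decoy
  name <- sprintf("%s%03d",
                  ifelse(seq_len(n_tot) <= spec$n_informative, "inf", "dcy"),
                  seq_len(n_tot))
  if (is.null(features)) features <- name
  idx <- match(features, name)
  stopifnot(!anyNA(idx))
  value <- function(x) {
    out <- matrix(0, length(x), length(idx),
                  dimnames = list(NULL, features))
    for (c in seq_along(idx))
      if (idx[c] <= spec$n_informative)
        out[, c] <- link_value(links[[idx[c]]], x)
    out
  }
  deriv <- function(x) {
    out <- matrix(0, length(x), length(idx),
                  dimnames = list(NULL, features))
    for (c in seq_along(idx))
      if (idx[c] <= spec$n_informative)
        out[, c] <- link_deriv(links[[idx[c]]], x)
    out
  }
  list(value = value, deriv = deriv, features = features)
}
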