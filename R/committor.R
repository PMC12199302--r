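#' Absorbing states on the latent transition coordinate
#'
#' Defines commitment of a shot trajectory by absorbing thresholds on the
#' transition coordinate: committed to `closed` once \eqn{x \le} the closed
#' boundary, to `S1` once \eqn{x \ge} the S1 boundary.  These match the
#' boundaries of [analytic_committor_1d()], so shooting estimates can be
#' compared with the exact oracle.
#'
#' @param closed Upper edge of the closed (reactant) state.
#' @param s1 Lower edge of the S1 (product) state; must exceed `closed`.
#' @return Object of class `interval_states`.
#' @export
interval_states <- function(closed = -1, s1 = 1) {
  stopifnot(closed < s1)
  structure(list(closed = closed, s1 = s1), class = "interval_states")
}

#' Shooting configuration
#'
#' @param n_shots Number of independent relaxations per snapshot
#'   (default 100).
#' @param max_steps Step budget per shot.
#' @param timestep,friction,kT Engine parameters for the shots; fresh,
#'   independent noise streams per shot play the role of resampled
#'   Maxwell-Boltzmann velocities in an inertial engine.
#' @export
shooting_config <- function(n_shots = 100L, max_steps = 5000L,
                            timestep = 0.01, friction = 1, kT = 1) {
  stopifnot(n_shots >= 1, max_steps >= 1, timestep > 0, friction > 0, kT > 0)
  structure(list(n_shots = as.integer(n_shots),
                 max_steps = as.integer(max_steps), timestep = timestep,
                 friction = friction, kT = kT),
            class = "shooting_config")
}

#' Estimate the committor of a snapshot by shooting
#'
#' Launches `n_shots` independent overdamped relaxations from the snapshot
#' with fresh noise, terminating each at first entry into the closed or S1
#' state (or at `max_steps`).  The committor estimate
#' \eqn{p = n_{S1} / (n_{S1} + n_{closed})} uses committed shots only;
#' uncommitted shots are counted separately.
#'
#' @param snapshot Latent starting point.
#' @param potential A `model_potential`.
#' @param states An `interval_states`.
#' @param cfg A `shooting_config`.
#' @param seed Master seed; the per-record RNG stream is derived
#'   deterministically so any record is exactly reproducible.
#' @return A `committor_record`: list with `p`, `n_to_s1`, `n_to_closed`,
#'   `n_uncommitted`, `n_shots`, `seed`, `snapshot`, `valid`.
#' @export
shoot <- function(snapshot, potential, states, cfg = shooting_config(),
                  seed = 1L) {
  stopifnot(inherits(potential, "model_potential"),
            inherits(states, "interval_states"),
            inherits(cfg, "shooting_config"))
  d <- potential$dimensionality
  x0 <- matrix(rep(as_latent_point(snapshot, d), each = cfg$n_shots),
               cfg$n_shots, d)
  set.seed(derive_seed(seed, 1L))
  res <- propagate_committed(potential, x0, states$closed, states$s1,
                             cfg$timestep, cfg$friction, cfg$kT,
                             cfg$max_steps)
  n_s1 <- sum(res$outcome == 1L)
  n_closed <- sum(res$outcome == -1L)
  n_un <- sum(res$outcome == 0L)
  valid <- (n_s1 + n_closed) > 0L
  if (!valid)
    warning("all ", cfg$n_shots, " shots uncommitted; record flagged invalid")
  structure(list(p = if (valid) n_s1 / (n_s1 + n_closed) else NA_real_,
                 n_to_s1 = n_s1, n_to_closed = n_closed, n_uncommitted = n_un,
                 n_shots = cfg$n_shots, seed = seed,
                 snapshot = as_latent_point(snapshot, d), valid = valid),
            class = "committor_record")
}

#' @export
print.committor_record <- function(x, ...) {
  cat("<committor_record> p =", signif(x$p, 4), " (", x$n_to_s1, "to S1,",
      x$n_to_closed, "to closed,", x$n_uncommitted, "uncommitted )\n")
  invisible(x)
}

#' Harvest reactive-region snapshots from projected paths
#'
#' Collects every frame whose 2D CV projection falls in the reactive
#' rectangle of a [state_definition()], skipping blacklisted paths (manual
#' exclusions of irreproducible paths are expressed this way).
#'
#' @param projections List of per-path n_frames x 2 CV matrices.
#' @param def A `state_definition`.
#' @param blacklist Integer path ids to exclude.
#' @return Data frame with columns `path_id`, `frame`, `cv1`, `cv2`; zero
#'   rows (with a warning) when nothing is harvested.
#' @export
harvest_reactive_snapshots <- function(projections, def, blacklist = integer()) {
  stopifnot(inherits(def, "state_definition"))
  out <- list()
  for (p in seq_along(projections)) {
    if (p %in% blacklist) next
    pr <- as.matrix(projections[[p]])
    lab <- assign_state(pr, def)
    i <- which(lab == "reactive")
    if (length(i) > 0)
      out[[length(out) + 1]] <- data.frame(path_id = p, frame = i,
                                           cv1 = pr[i, 1], cv2 = pr[i, 2])
  }
  if (length(out) == 0) {
    warning("no reactive-region snapshots harvested")
    return(data.frame(path_id = integer(), frame = integer(),
                      cv1 = numeric(), cv2 = numeric()))
  }
  do.call(rbind, out)
}

#' Committor dataset
#'
#' Couples committor records with their snapshot feature vectors and split
#' labels.  Splits are stratified on the committor so each split covers
#' committor values near-uniformly.
#'
#' @param records Data frame with at least columns `p` (committor) and an
#'   id; one row per snapshot.
#' @param features Numeric matrix of snapshot feature vectors, rows aligned
#'   with `records`, named columns.
#' @param n_bins Number of committor strata (default 10).
#' @return Object of class `committor_dataset`.
#' @export
committor_dataset <- function(records, features, n_bins = 10L) {
  features <- as.matrix(features)
  stopifnot(nrow(records) == nrow(features), !is.null(colnames(features)),
            all(records$p >= 0 & records$p <= 1))
  records$bin <- committor_bin(records$p, n_bins)
  structure(list(records = records, features = features,
                 n_bins = as.integer(n_bins)),
            class = "committor_dataset")
}

# sample() treats a length-one integer as 1:n; index first
resample <- function(x, n, replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}

committor_bin <- function(p, n_bins) {
  b <- findInterval(p, seq(0, 1, length.out = n_bins + 1),
                    rightmost.closed = TRUE)
  pmin(pmax(b, 1L), n_bins)
}

#' @export
print.committor_dataset <- function(x, ...) {
  cat("<committor_dataset>", nrow(x$records), "records x",
      ncol(x$features), "features;", x$n_bins, "committor bins\n")
  if (!is.null(x$records$split)) print(table(x$records$split))
  invisible(x)
}

#' Stratified subsample of committor records
#'
#' Draws up to `n_target` records with committor-bin counts as uniform as
#' the pool allows: every bin contributes at least `min(bin size,
#' n_target / n_bins)` records and any remainder is spread over the bins
#' with surplus records.  Used to turn a bimodal harvest (most snapshots
#' near-committed) into a balanced committor dataset.
#'
#' @param dataset A `committor_dataset`.
#' @param n_target Number of records to keep.
#' @param seed Seed for the within-bin draws.
#' @return A `committor_dataset` with the subsampled records.
#' @export
stratified_subsample <- function(dataset, n_target, seed = 1L) {
  stopifnot(inherits(dataset, "committor_dataset"), n_target >= 1)
  rec <- dataset$records
  if (nrow(rec) <= n_target) return(dataset)
  by_bin <- split(seq_len(nrow(rec)), rec$bin)
  sizes <- lengths(by_bin)
  take <- pmin(sizes, ceiling(n_target / length(by_bin)))
  left <- n_target - sum(take)
  while (left > 0) {
    surplus <- sizes - take
    if (all(surplus == 0)) break
    # spread the remainder as evenly as the surplus allows
    elig <- which(surplus > 0)
    for (i in elig[order(-surplus[elig])]) {
      if (left == 0) break
      take[i] <- take[i] + 1L
      left <- left - 1L
    }
  }
  while (sum(take) > n_target) {
    i <- which.max(take)
    take[i] <- take[i] - (sum(take) - n_target)
  }
  set.seed(seed)
  keep <- sort(unlist(lapply(seq_along(by_bin), function(b)
    if (take[b] >= sizes[b]) by_bin[[b]] else resample(by_bin[[b]],
                                                       take[b]))))
  committor_dataset(rec[keep, setdiff(names(rec), "bin"), drop = FALSE],
                    dataset$features[keep, , drop = FALSE], dataset$n_bins)
}

#' Stratified test/validation/training partition of committor records
#'
#' Bins the committor range and draws equal numbers per bin into the test
#' set (and optionally a validation set), so distinct committor values have
#' near-identical probabilities within each split.
#'
#' @param dataset A `committor_dataset`.
#' @param test_count Total test-set size (divided evenly over the bins).
#' @param validation_frac Fraction of the remainder assigned (stratified) to
#'   a validation split; the rest is the training pool.
#' @param seed Seed for the draws.
#' @return The dataset with a `split` column
#'   (`"test"`/`"validation"`/`"training"`).
#' @export
stratified_partition <- function(dataset, test_count, validation_frac = 0.10,
                                 seed = 1L) {
  stopifnot(inherits(dataset, "committor_dataset"), test_count >= 1)
  rec <- dataset$records
  n_bins <- dataset$n_bins
  per_bin <- ceiling(test_count / n_bins)
  tab <- tabulate(rec$bin, n_bins)
  if (any(tab == 0))
    stop("empty committor bin(s): ",
         paste(which(tab == 0), collapse = ", "),
         "; cannot stratify the partition")
  if (any(tab < per_bin))
    stop("committor bin(s) ", paste(which(tab <= per_bin), collapse = ", "),
         " too small for ", per_bin, " test draws per bin")
  set.seed(seed)
  rec$split <- "training"
  for (b in seq_len(n_bins)) {
    i <- which(rec$bin == b)
    test_i <- resample(i, per_bin)
    rec$split[test_i] <- "test"
    rest <- setdiff(i, test_i)
    n_val <- round(validation_frac * length(rest))
    if (n_val > 0) rec$split[resample(rest, n_val)] <- "validation"
  }
  dataset$records <- rec
  dataset
}

#' Stratified bootstrap replicates of a committor pool
#'
#' Resamples with replacement within each committor bin, so every replicate
#' preserves the pool's per-bin proportions to within one record and has the
#' same total size as the pool.
#'
#' @param dataset A `committor_dataset`.
#' @param pool Row indices to resample (e.g. the training pool).
#' @param n_replicates Number of replicates.
#' @param seed Master seed; per-replicate seeds are derived and recorded.
#' @return List of integer index vectors, each of `length(pool)`, with
#'   attribute `seeds`.
#' @export
bootstrap_resample <- function(dataset, pool, n_replicates, seed = 1L) {
  stopifnot(inherits(dataset, "committor_dataset"), length(pool) >= 1,
            n_replicates >= 1)
  bins <- dataset$records$bin[pool]
  by_bin <- split(pool, bins)
  seeds <- vapply(seq_len(n_replicates), function(r) derive_seed(seed, r),
                  integer(1))
  reps <- lapply(seq_len(n_replicates), function(r) {
    set.seed(seeds[r])
    unlist(lapply(by_bin, function(i) resample(i, length(i),
                                               replace = TRUE)),
           use.names = FALSE)
  })
  attr(reps, "seeds") <- seeds
  reps
}

#' Write / read a committor dataset as TSV
#'
#' @param dataset A `committor_dataset`.
#' @param path File path.
#' @export
write_committor_tsv <- function(dataset, path) {
  df <- cbind(dataset$records, as.data.frame(dataset$features))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#! ", jsonlite::toJSON(
    list(n_bins = dataset$n_bins, n_features = ncol(dataset$features),
         feature_names = colnames(dataset$features)),
    auto_unbox = TRUE)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_committor_tsv
#' @export
read_committor_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(sub("^#! ", "", lines[1]))
  df <- utils::read.table(text = lines[-1], header = TRUE, sep = "\t",
                          check.names = FALSE)
  feats <- as.matrix(df[, hdr$feature_names, drop = FALSE])
  rec <- df[, setdiff(names(df), hdr$feature_names), drop = FALSE]
  ds <- committor_dataset(rec[, setdiff(names(rec), "bin"), drop = FALSE],
                          feats, hdr$n_bins)
  ds
}
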