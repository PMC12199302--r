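#' Pipeline configuration with validated defaults
#'
#' Collects every stage parameter in one validated list.  Defaults are the
#' analysis-scale values used throughout: 0.45 nm contact cutoff, 70%
#' persistence under 5-fold symmetry, coordination r0 0.3 nm with exponent
#' 6, |r| > 0.25 PC1-template filter, 2 contact / 5 distance principal
#' components, 100 shots per committor point, |r| > 0.1 committor filter,
#' Leiden resolutions 0.6 (feature clustering), 0.7 (merge threshold) and
#' 0.2 (CV splitting), 20/300 bootstrap replicates, a 1000-proposal by
#' 100-repeat Monte-Carlo search retaining features present in 17% of final
#' subsets at p <= 0.05, transition-state stripe [-0.25, 0.25], umbrella
#' window width 0.5 with a 50 kJ/mol bias, 320 K, and -110 mV.
#'
#' @param ... Named overrides of the defaults.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    contact_cutoff = 0.45, persistence = 0.70, symmetry_fold = 5L,
    coord_r0 = 0.3, coord_exponent = 6L,
    template_threshold = 0.25, pcs_contacts = 2L, pcs_distances = 5L,
    n_shots = 100L, committor_threshold = 0.1,
    gamma_cluster = 0.6, merge_threshold = 0.7, gamma_split = 0.2,
    test_count = 30L, validation_frac = 0.10,
    n_boot_search = 20L, n_boot_final = 300L,
    mc_iterations = 1000L, n_repeats = 100L,
    retention_fraction = 0.17, p_threshold = 0.05,
    ts_stripe = c(-0.25, 0.25),
    window_width = 0.5, bias_kjmol = 50, temperature = 320,
    voltage_mV = -110,
    blacklist = integer(), seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  with(cfg, {
    stopifnot(contact_cutoff > 0, persistence > 0, persistence <= 1,
              symmetry_fold >= 1, coord_r0 > 0, coord_exponent >= 2,
              template_threshold >= 0, pcs_contacts >= 1, pcs_distances >= 1,
              n_shots >= 1, committor_threshold >= 0, gamma_cluster > 0,
              merge_threshold > 0, gamma_split > 0, test_count >= 1,
              validation_frac > 0, validation_frac < 1,
              n_boot_search >= 2, n_boot_final >= 2, mc_iterations >= 1,
              n_repeats >= 1, retention_fraction > 0,
              retention_fraction <= 1, p_threshold > 0,
              ts_stripe[1] < ts_stripe[2], window_width > 0, bias_kjmol > 0,
              temperature > 0)
  })
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-20s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}

#' Default benchmark system: 2D double well with harmonic orthogonal mode
#'
#' The study system for desk-scale validation: a quartic double well along
#' the transition coordinate (wells at -1 and +1, 4 kT barrier) plus one
#' harmonic orthogonal mode, sampled by overdamped dynamics at kT = 1.
#'
#' @param barrier_height Barrier in kT (default 4).
#' @param tilt Well asymmetry in kT (default 0, symmetric).
#' @return List with `potential`, `params`, `state_bounds`, `states`
#'   (absorbing `interval_states`), `kT`.
#' @export
benchmark_system <- function(barrier_height = 4, tilt = 0) {
  potential <- potential_double_well(barrier_height = barrier_height,
                                     well_positions = c(-1, 1), tilt = tilt,
                                     orthogonal_stiffness = 4,
                                     dimensionality = 2)
  params <- langevin_params(timestep = 0.01, friction = 1, kT = 1,
                            n_steps = 60000L, save_interval = 2L)
  list(potential = potential, params = params,
       state_bounds = list(closed = c(-1.4, -0.7), s1 = c(0.7, 1.4)),
       states = interval_states(closed = -0.7, s1 = 0.7), kT = 1)
}

#' Run the full synthetic benchmark pipeline
#'
#' End-to-end study on the planted system: generate reactive paths, embed
#' them into a synthetic feature table (informative + decoy + collinear
#' features), build the two SVM collective variables, derive density-based
#' state regions, harvest reactive snapshots, estimate committors by
#' shooting, and optimize the reaction coordinate by Monte-Carlo feature
#' selection with bootstrap coefficient finalization.  All randomness
#' derives from `seed`; two calls with the same seed give identical numeric
#' outputs.
#'
#' @param seed Master seed.
#' @param config A `pipeline_config`; the default uses a reduced Monte-Carlo
#'   search budget suited to the 60-feature planted problem (see the
#'   methods vignette).
#' @param n_paths Reactive paths to generate (default 12).
#' @param n_committor Committor points to shoot (default 300).
#' @param embedding A `feature_embedding_spec` (default: 5 informative
#'   among 55 decoys with two collinear blocks of 5 at target 0.9).
#' @param selection_seeds Seeds for repeated feature-selection runs
#'   (default: one run at the master seed).
#' @return List with all stage artifacts (see the vignette for a tour).
#' @export
run_benchmark <- function(seed = 1L,
                          config = pipeline_config(mc_iterations = 150L,
                                                   n_repeats = 12L),
                          n_paths = 12L, n_committor = 300L,
                          embedding = NULL,
                          selection_seeds = derive_seed(seed, 33L)) {
  stopifnot(inherits(config, "pipeline_config"))
  sys <- benchmark_system()
  if (is.null(embedding))
    embedding <- feature_embedding_spec(seed = derive_seed(seed, 2L))

  ## 1. reactive paths with dwell context in both wells
  paths <- generate_transition_paths(sys$potential, sys$params,
                                     sys$state_bounds, n_paths,
                                     seed = derive_seed(seed, 1L))

  ## 2. feature embedding (shared links, per-path noise)
  fms <- lapply(seq_along(paths), function(i)
    embed_features(paths[[i]], embedding,
                   noise_seed = derive_seed(seed, 100L + i)))
  pooled <- fm_pool(fms)
  path_id <- attr(pooled, "path_id")

  ## 2b. PC1 transition template from the contact-like family, then screen
  ##     every feature against it at |r| > template_threshold
  tmpl <- pc1_template(lapply(fms, function(f)
    fm_select(f, which(f$meta$kind == "synthetic-contact"))))
  screened <- correlation_select(pooled, tmpl$pooled,
                                 threshold = config$template_threshold)
  attr(screened, "path_id") <- path_id

  ## 3. two SVM-based collective variables (contact-like / distance-like)
  fam_c <- fm_select(screened, which(screened$meta$kind == "synthetic-contact"))
  fam_d <- fm_select(screened, which(screened$meta$kind == "synthetic-distance"))
  attr(fam_c, "path_id") <- path_id; attr(fam_d, "path_id") <- path_id
  labels <- label_terminal_frames(path_id, 0.10)
  cv_contacts <- fit_svm_cv(
    pca_reduce(fam_c, min(config$pcs_contacts, ncol(fam_c$values))), labels)
  cv_distances <- fit_svm_cv(
    pca_reduce(fam_d, min(config$pcs_distances, ncol(fam_d$values))), labels)
  projections <- lapply(fms, function(f)
    cbind(predict(cv_contacts, f), predict(cv_distances, f)))

  ## 4. density-based state regions and snapshot harvest
  def <- density_regions(do.call(rbind, projections), bins = 100,
                         high_density_quantile = 0.90)
  snaps <- harvest_reactive_snapshots(projections, def,
                                      blacklist = config$blacklist)

  ## 5. committor shooting at the harvested snapshots
  shoot_cfg <- shooting_config(n_shots = config$n_shots, max_steps = 3000L,
                               timestep = sys$params$timestep,
                               friction = sys$params$friction, kT = sys$kT)
  latent <- t(vapply(seq_len(nrow(snaps)), function(i)
    paths[[snaps$path_id[i]]]$coords[snaps$frame[i], ],
    numeric(sys$potential$dimensionality)))
  recs <- lapply(seq_len(nrow(snaps)), function(i)
    shoot(latent[i, ], sys$potential, sys$states, shoot_cfg,
          seed = derive_seed(seed, 1000L + i)))
  records <- data.frame(id = seq_len(nrow(snaps)),
                        path_id = snaps$path_id, frame = snaps$frame,
                        p = vapply(recs, `[[`, numeric(1), "p"),
                        n_to_s1 = vapply(recs, `[[`, numeric(1), "n_to_s1"),
                        n_to_closed = vapply(recs, `[[`, numeric(1),
                                             "n_to_closed"),
                        n_uncommitted = vapply(recs, `[[`, numeric(1),
                                               "n_uncommitted"),
                        latent_x = latent[, 1])
  keep <- vapply(recs, `[[`, logical(1), "valid")
  records <- records[keep, ]
  feats <- do.call(rbind, lapply(seq_len(nrow(records)), function(i)
    fms[[records$path_id[i]]]$values[records$frame[i],
                                     screened$meta$name, drop = FALSE]))
  dataset <- committor_dataset(records, feats, n_bins = 10L)
  # balance the bimodal harvest into a near-uniform committor set
  dataset <- stratified_subsample(dataset, n_committor,
                                  seed = derive_seed(seed, 3L))
  latent <- as.matrix(dataset$records[, "latent_x", drop = FALSE])
  dataset <- stratified_partition(dataset, config$test_count,
                                  config$validation_frac,
                                  seed = derive_seed(seed, 4L))

  ## 6. decorrelate: committor filter, Leiden clustering, PC1 reduction
  pool_rows <- which(dataset$records$split != "test")
  filt <- committor_corr_filter(dataset$features[pool_rows, , drop = FALSE],
                                dataset$records$p[pool_rows],
                                threshold = config$committor_threshold)
  clusters <- correlation_cluster(filt, gamma = config$gamma_cluster,
                                  seed = derive_seed(seed, 5L))
  reduced <- cluster_pc1_reduce(filt, clusters,
                                merge_threshold = config$merge_threshold)
  red_all <- reduce_transform(reduced, dataset$features[, colnames(filt),
                                                        drop = FALSE])
  rdataset <- committor_dataset(dataset$records, red_all, n_bins = 10L)

  ## 7. Monte-Carlo feature selection (possibly at several seeds)
  searches <- lapply(selection_seeds, function(s)
    mc_feature_search(rdataset,
                      selection_config(n_boot = config$n_boot_search,
                                       mc_iterations = config$mc_iterations,
                                       n_repeats = config$n_repeats,
                                       retention_fraction =
                                         config$retention_fraction,
                                       p_threshold = config$p_threshold,
                                       seed = s)))
  selected <- searches[[1]]$selected
  if (length(selected) == 0)
    stop("feature selection returned an empty set on the benchmark")

  ## 8. bootstrap coefficient finalization -> optimized RC
  fit <- finalize_coefficients(rdataset, selected,
                               n_boot = config$n_boot_final,
                               seed = derive_seed(seed, 6L))
  z_all <- predict(fit, type = "cv")
  diag <- ts_diagnostics(dataset$records$p, z_all,
                         stripe = config$ts_stripe)
  cv_opt <- rc_as_linear_cv(fit, reduced)

  list(config = config, seed = seed, system = sys, embedding = embedding,
       paths = paths, feature_matrices = fms,
       cv_contacts = cv_contacts, cv_distances = cv_distances,
       state_definition = def, dataset = dataset, reduced = reduced,
       reduced_dataset = rdataset, searches = searches,
       selected = selected, fit = fit, cv_optimized = cv_opt,
       cv_values = z_all, ts_diagnostics = diag,
       latent = latent)
}

#' Score a feature selection against the planted ground truth
#'
#' A selected reduced feature counts as informative when any of its member
#' features is a planted informative feature.  Reports whether every planted
#' informative feature is covered by the selection and the precision of the
#' selection against decoys.
#'
#' @param selected Selected reduced-feature names.
#' @param reduced The `reduced_feature_set`.
#' @param embedding The `feature_embedding_spec` that planted the features.
#' @return List with `informative_covered` (count), `n_informative`,
#'   `all_covered` (logical), `precision`.
#' @export
score_selection <- function(selected, reduced, embedding) {
  inf_names <- sprintf("inf%03d", seq_len(embedding$n_informative))
  rnames <- vapply(reduced$maps, function(m) m$provenance$reduced %||% "",
                   character(1))
  members <- lapply(reduced$maps, `[[`, "features")
  sel_members <- members[match(selected, rnames)]
  covered <- inf_names[inf_names %in% unlist(sel_members)]
  is_inf <- vapply(sel_members, function(m) any(m %in% inf_names),
                   logical(1))
  list(informative_covered = length(covered),
       n_informative = length(inf_names),
       all_covered = length(covered) == length(inf_names),
       precision = if (length(is_inf) > 0) mean(is_inf) else NA_real_)
}

#' Umbrella-sampling free energy along the benchmark's optimized CV
#'
#' Runs replicate umbrella scans along the optimized reaction coordinate on
#' the latent engine (harmonic bias through the embedding's smooth mean map
#' by the chain rule), unbiases each replicate with WHAM, averages the
#' replicate profiles, and derives the 1RT basins, barrier and basin
#' free-energy difference.  Energies are in kT; multiply by
#' [rt_kjmol()] to report kJ/mol.
#'
#' @param bench A [run_benchmark()] result.
#' @param n_replicates Independent umbrella scans averaged (default 4,
#'   mirroring replicate-path averaging).
#' @param production,equilibration Per-window simulation times (engine time
#'   units).
#' @param bin_width WHAM bin width in CV units.
#' @param seed Master seed.
#' @return List with `profile` (averaged `free_energy_profile`, kT units),
#'   `replicates`, `basins`, `delta_f`, `cvfun`, `centers`.
#' @export
benchmark_free_energy <- function(bench, n_replicates = 4L, production = 25,
                                  equilibration = 3, bin_width = 0.25,
                                  seed = 1L) {
  cfg <- bench$config
  k_kt <- cfg$bias_kjmol / rt_kjmol(cfg$temperature)
  cvfun <- cv_on_latent(bench$cv_optimized, bench$embedding)
  zx <- cvfun$value(seq(-1.3, 1.3, length.out = 201))
  centers <- seq(min(zx) + cfg$window_width / 2,
                 max(zx) - cfg$window_width / 2, by = cfg$window_width)
  # stable integration under a stiff bias through a steep CV
  dt <- min(0.2 / (k_kt * cvfun$max_slope^2 + 40), 0.002)
  par <- langevin_params(timestep = dt, friction = 1, kT = 1)
  zseries <- lapply(bench$paths, function(p) cvfun$value(p$coords[, 1]))
  seeds_df <- select_window_seeds(zseries, centers,
                                  width = cfg$window_width)
  x0s <- t(vapply(seq_along(centers), function(i)
    bench$paths[[seeds_df$path_id[i]]]$coords[seeds_df$frame[i], ],
    numeric(bench$system$potential$dimensionality)))
  profiles <- lapply(seq_len(n_replicates), function(r) {
    series <- run_biased_ensemble(bench$system$potential, par, cvfun,
                                  centers, k_kt, equilibration, production,
                                  x0s, seed = derive_seed(seed, 1000L * r))
    wham_unbias(series, centers, force_constant = k_kt, kT = 1,
                bin_width = bin_width)
  })
  avg <- average_profiles(profiles)
  # the CV saturates outside the wells (vanishing dz/dx), which bends the
  # marginal down again beyond them; basin analysis is restricted to the
  # window-covered core between the well images
  core <- avg[avg$z >= min(centers) & avg$z <= max(centers), , drop = FALSE]
  core$free_energy <- core$free_energy - min(core$free_energy)
  class(core) <- class(avg)
  basins <- basin_bounds(core, rt = 1, smooth = 5)
  list(profile = avg, core = core, replicates = profiles, basins = basins,
       delta_f = free_energy_difference(core, basins, rt = 1),
       cvfun = cvfun, centers = centers, timestep = dt,
       force_constant_kt = k_kt)
}

#' First-passage kinetics of the benchmark along the optimized CV
#'
#' Runs one long unbiased equilibrium trajectory, projects it onto the
#' optimized CV, extracts successive committed closed-to-S1 transition
#' times, fits the exponential law to them, tests exponentiality with the
#' two-sample KS procedure, measures the 1RT-level attempt frequency, and
#' compares the empirical mean transition time with the
#' Eyring-Polanyi estimate from the free-energy barrier.
#'
#' @param bench A [run_benchmark()] result.
#' @param fep A [benchmark_free_energy()] result (for basins and barrier).
#' @param n_steps Length of the equilibrium run.
#' @param seed Seed.
#' @return List with `times`, `fit` (`exponential_fit`), `ks`, `nu_c`,
#'   `tst` (k and mean time from the barrier), `ratio`
#'   (empirical tau / TST tau).
#' @export
benchmark_kinetics <- function(bench, fep, n_steps = 600000L, seed = 1L) {
  par <- langevin_params(timestep = 0.01, friction = 1, kT = 1,
                         n_steps = as.integer(n_steps), save_interval = 2L,
                         seed = derive_seed(seed, 77L))
  traj <- simulate_overdamped(bench$system$potential, par, c(-1, 0))
  z <- fep$cvfun$value(traj$coords[, 1])
  times <- recurrent_transition_times(z, traj$times, fep$basins)
  fit <- fit_exponential(times)
  ks <- ks_two_sample_exponential(times, fit$tau, n_theory = 1e5,
                                  seed = derive_seed(seed, 78L))
  nu_c <- crossing_frequency(z, traj$times, level = fep$basins$closed[2],
                             fep$basins)
  k_tst <- as.numeric(nu_c) * exp(-fep$basins$barrier_height)
  list(times = times, fit = fit, ks = ks, nu_c = as.numeric(nu_c),
       tst = list(k_tst = k_tst, mean_time = 1 / k_tst),
       ratio = fit$tau * k_tst)
}

#' Successive committed transition times from one long equilibrium series
#'
#' Segments a long CV series into successive closed-to-S1 passages: after
#' each committed crossing the search restarts at the next re-entry into
#' the closed basin.  Used to build first-passage statistics from a single
#' equilibrium run.
#'
#' @param z CV series.
#' @param times Time stamps.
#' @param basins A `basin_bounds`.
#' @return Numeric vector of elapsed transition times (possibly empty).
#' @export
recurrent_transition_times <- function(z, times, basins) {
  out <- numeric(0)
  i <- 1L
  n <- length(z)
  cl <- basins$closed; s1 <- basins$s1; bar <- basins$barrier_position
  while (i <= n) {
    entry <- which(z[i:n] >= cl[1] & z[i:n] <= cl[2])[1]
    if (is.na(entry)) break
    entry <- i + entry - 1L
    j <- entry
    done <- FALSE
    while (j <= n && !done) {
      cross <- which(z[j:n] > bar)[1]
      if (is.na(cross)) break
      cross <- j + cross - 1L
      k <- cross
      committed <- NA
      while (k <= n) {
        if (z[k] >= s1[1]) { committed <- TRUE; break }
        if (z[k] <= cl[2]) { committed <- FALSE; break }
        k <- k + 1L
      }
      if (isTRUE(committed)) {
        out <- c(out, times[cross] - times[entry])
        # restart once the system has relaxed back into the closed basin
        i <- k + 1L
        done <- TRUE
      } else if (is.na(committed)) {
        return(out)
      } else {
        j <- k
      }
    }
    if (!done) break
  }
  out
}
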