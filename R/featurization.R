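ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                   P = 30.974, FE = 55.845, ZN = 65.38, MG = 24.305,
                   K = 39.098, CL = 35.45, NA. = 22.99)

atom_mass <- function(element) {
  el <- toupper(element)
  el[el == "NA"] <- "NA."
  m <- ATOMIC_MASSES[el]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Structural trajectory container
#'
#' Multi-frame structure with a fixed atom roster.  Coordinates are stored in
#' nanometres; `read_pdb_trajectory` converts from the PDB's angstroms.
#'
#' @param atoms Data frame with columns `eleno`, `elety` (atom name),
#'   `element`, `resno`, `chain`; a `mass` column is added if missing and a
#'   logical `heavy` column marks non-hydrogen atoms.
#' @param coords Numeric array frames x atoms x 3 (nm), or a single
#'   atoms x 3 matrix for one frame.
#' @param times Frame time stamps.
#' @return Object of class `structure_trajectory`.
#' @export
structure_trajectory <- function(atoms, coords, times = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(1, nrow(coords), 3))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == nrow(atoms),
            dim(coords)[3] == 3, all(is.finite(coords)))
  if (is.null(times)) times <- seq_len(dim(coords)[1])
  if (is.null(atoms$element))
    atoms$element <- sub("^[0-9]*([A-Za-z]).*", "\\1", atoms$elety)
  if (is.null(atoms$mass)) atoms$mass <- atom_mass(atoms$element)
  atoms$heavy <- toupper(atoms$element) != "H"
  structure(list(atoms = atoms, coords = coords, times = as.numeric(times)),
            class = "structure_trajectory")
}

#' @export
print.structure_trajectory <- function(x, ...) {
  cat("<structure_trajectory>", dim(x$coords)[1], "frames,",
      nrow(x$atoms), "atoms,", length(unique(x$atoms$chain)), "chains\n")
  invisible(x)
}

#' Read a multi-model PDB file as a structure trajectory
#'
#' MODEL/ENDMDL records define the frames; coordinates are converted from
#' angstrom to nm.  Requires the bio3d package.
#'
#' @param path PDB file path.
#' @param dt Time spacing assigned to successive models.
#' @return A `structure_trajectory`.
#' @export
read_pdb_trajectory <- function(path, dt = 1) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB trajectories requires the bio3d package")
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz                       # models x (3 * natoms), angstrom
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz); n_atoms <- ncol(xyz) / 3
  coords <- array(NA_real_, c(n_frames, n_atoms, 3))
  for (f in seq_len(n_frames))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10
  atoms <- data.frame(eleno = pdb$atom$eleno, elety = pdb$atom$elety,
                      element = pdb$atom$elesy, resno = pdb$atom$resno,
                      chain = pdb$atom$chain, stringsAsFactors = FALSE)
  structure_trajectory(atoms, coords, times = (seq_len(n_frames) - 1) * dt)
}

resolve_residue <- function(traj, res) {
  if (is.character(res) && length(res) == 1) {
    parts <- strsplit(res, ":", fixed = TRUE)[[1]]
    res <- list(chain = parts[1], resno = as.integer(parts[2]))
  }
  idx <- which(traj$atoms$chain == res$chain & traj$atoms$resno == res$resno)
  if (length(idx) == 0)
    stop("residue ", res$chain, ":", res$resno, " not found")
  idx
}

#' Minimum heavy-atom distance between two residues
#'
#' @param traj A `structure_trajectory`.
#' @param frame Frame index.
#' @param res_a,res_b Residues, as `"chain:resno"` strings or
#'   `list(chain =, resno =)`.
#' @param heavy_only Restrict to non-hydrogen atoms (default TRUE).
#' @return Distance in nm.  Identical residues give 0 with attribute
#'   `degenerate = TRUE` (invalid for contact use).
#' @export
min_residue_distance <- function(traj, frame, res_a, res_b,
                                 heavy_only = TRUE) {
  ia <- resolve_residue(traj, res_a); ib <- resolve_residue(traj, res_b)
  if (heavy_only) {
    ia <- ia[traj$atoms$heavy[ia]]; ib <- ib[traj$atoms$heavy[ib]]
    if (length(ia) == 0 || length(ib) == 0)
      stop("residue without heavy atoms in min_residue_distance")
  }
  a <- traj$coords[frame, ia, , drop = FALSE]
  b <- traj$coords[frame, ib, , drop = FALSE]
  d2 <- outer(seq_along(ia), seq_along(ib), function(i, j) {
    (a[1, i, 1] - b[1, j, 1])^2 + (a[1, i, 2] - b[1, j, 2])^2 +
      (a[1, i, 3] - b[1, j, 3])^2
  })
  out <- sqrt(min(d2))
  if (identical(sort(ia), sort(ib))) attr(out, "degenerate") <- TRUE
  out
}

#' Contact specification
#'
#' @param cutoff Heavy-atom minimum-distance cutoff in nm (default 0.45 nm,
#'   i.e. 4.5 angstrom).
#' @param persistence Minimum occupied fraction of all possible instances
#'   (frames x symmetry_fold) for a contact class to be retained.
#' @param symmetry_fold Rotational symmetry order used to pool equivalent
#'   inter-chain contacts (5 for a homopentamer).
#' @export
contact_spec <- function(cutoff = 0.45, persistence = 0.70,
                         symmetry_fold = 5L) {
  stopifnot(cutoff > 0, persistence > 0, persistence <= 1, symmetry_fold >= 1)
  structure(list(cutoff = cutoff, persistence = persistence,
                 symmetry_fold = as.integer(symmetry_fold)),
            class = "contact_spec")
}

# residue-pair minimum distances for one frame: returns matrix over the
# residue table (rows = residue units in `units`)
frame_min_dist <- function(traj, frame, units, heavy_only = TRUE) {
  xyz <- traj$coords[frame, , ]
  keep <- if (heavy_only) traj$atoms$heavy else rep(TRUE, nrow(traj$atoms))
  n <- length(units)
  d <- matrix(Inf, n, n)
  idx <- lapply(units, function(u) u$idx[keep[u$idx]])
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (length(idx[[i]]) == 0 || length(idx[[j]]) == 0) next
    a <- xyz[idx[[i]], , drop = FALSE]; b <- xyz[idx[[j]], , drop = FALSE]
    cross <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    d[i, j] <- d[j, i] <- sqrt(max(min(cross), 0))
  }
  d
}

residue_units <- function(traj) {
  key <- paste(traj$atoms$chain, traj$atoms$resno, sep = ":")
  split_idx <- split(seq_len(nrow(traj$atoms)), key)
  lapply(names(split_idx), function(k) {
    parts <- strsplit(k, ":", fixed = TRUE)[[1]]
    list(chain = parts[1], resno = as.integer(parts[2]), idx = split_idx[[k]])
  })
}

#' Persistent symmetry-pooled residue contacts
#'
#' Two residues are in contact in a frame when their minimum heavy-atom
#' distance is below `cutoff`.  Contacts are pooled over the rotational
#' symmetry: a contact class is identified by (smaller residue index, larger
#' residue index, chain-offset class mod `symmetry_fold`), so one frame can
#' contribute up to `symmetry_fold` instances of a class.  Classes occupied
#' in at least `persistence` of frames x symmetry_fold instances are kept.
#'
#' @param traj A `structure_trajectory` whose chains realize the symmetry.
#' @param spec A `contact_spec`.
#' @return Data frame with columns `res_i`, `res_j`, `offset`, `count`,
#'   `possible`, `fraction`, sorted by decreasing fraction.
#' @export
stable_contacts <- function(traj, spec = contact_spec()) {
  chains <- sort(unique(traj$atoms$chain))
  if (length(chains) < spec$symmetry_fold)
    stop("trajectory has ", length(chains), " chains but symmetry_fold = ",
         spec$symmetry_fold)
  units <- residue_units(traj)
  chain_rank <- match(vapply(units, `[[`, character(1), "chain"), chains) - 1L
  resno <- vapply(units, `[[`, integer(1), "resno")
  n_frames <- dim(traj$coords)[1]
  counts <- new.env(parent = emptyenv())
  for (f in seq_len(n_frames)) {
    d <- frame_min_dist(traj, f, units)
    hits <- which(d < spec$cutoff & upper.tri(d), arr.ind = TRUE)
    if (nrow(hits) == 0) next
    for (h in seq_len(nrow(hits))) {
      i <- hits[h, 1]; j <- hits[h, 2]
      key <- contact_class_key(resno[i], chain_rank[i], resno[j],
                               chain_rank[j], spec$symmetry_fold)
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  keys <- ls(counts)
  possible <- n_frames * spec$symmetry_fold
  if (length(keys) == 0)
    return(data.frame(res_i = integer(), res_j = integer(),
                      offset = integer(), count = integer(),
                      possible = integer(), fraction = numeric()))
  parts <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
  out <- data.frame(res_i = as.integer(parts[, 1]),
                    res_j = as.integer(parts[, 2]),
                    offset = as.integer(parts[, 3]),
                    count = vapply(keys, function(k) counts[[k]], integer(1)),
                    possible = possible)
  out$fraction <- out$count / out$possible
  out <- out[out$fraction >= spec$persistence, , drop = FALSE]
  out[order(-out$fraction), , drop = FALSE]
}

# class key: orient the pair so the smaller residue index comes first; the
# offset is the chain rotation from the first residue's chain to the second,
# mod the symmetry fold.  Ties in residue index take the smaller offset of
# the two orientations so labelling of chains never matters.
contact_class_key <- function(r1, c1, r2, c2, fold) {
  if (r1 > r2 || (r1 == r2 && ((c2 - c1) %% fold) > ((c1 - c2) %% fold))) {
    tmp <- r1; r1 <- r2; r2 <- tmp
    tmp <- c1; c1 <- c2; c2 <- tmp
  }
  paste(r1, r2, (c2 - c1) %% fold, sep = "_")
}

#' Coordination-number specification
#'
#' Smooth contact count via the rational switching function
#' \eqn{s_{ij} = 1 / (1 + (r_{ij}/r_0)^n)}.
#'
#' @param r0 Switching midpoint in nm (default 0.3 nm).
#' @param exponent Even integer >= 2 (default 6).
#' @export
coordination_spec <- function(r0 = 0.3, exponent = 6L) {
  stopifnot(r0 > 0, exponent >= 2, exponent %% 2 == 0)
  structure(list(r0 = r0, exponent = as.integer(exponent)),
            class = "coordination_spec")
}

#' Coordination number between two atom groups
#'
#' \eqn{C = \sum_{i \in A}\sum_{j \in B} 1/(1 + (r_{ij}/r_0)^n)}; smooth in
#' the coordinates, equal to 0.5 per pair at \eqn{r = r_0} and 1 as
#' \eqn{r \to 0}.
#'
#' @param traj A `structure_trajectory`.
#' @param frame Frame index.
#' @param group_a,group_b Disjoint, non-empty atom index vectors.
#' @param spec A `coordination_spec`.
#' @return Dimensionless coordination number.
#' @export
coordination_number <- function(traj, frame, group_a, group_b,
                                spec = coordination_spec()) {
  stopifnot(length(group_a) > 0, length(group_b) > 0,
            length(intersect(group_a, group_b)) == 0)
  a <- traj$coords[frame, group_a, , drop = FALSE]
  b <- traj$coords[frame, group_b, , drop = FALSE]
  am <- matrix(a[1, , ], ncol = 3); bm <- matrix(b[1, , ], ncol = 3)
  d2 <- outer(rowSums(am^2), rowSums(bm^2), "+") - 2 * am %*% t(bm)
  r <- sqrt(pmax(d2, 0))
  sum(1 / (1 + (r / spec$r0)^spec$exponent))
}

#' Helical-turn annotation
#'
#' @param turns Data frame with columns `turn_id`, `chain`, `res_from`,
#'   `res_to` (inclusive residue ranges, non-overlapping within a chain).
#' @export
turn_annotation <- function(turns) {
  stopifnot(all(c("turn_id", "chain", "res_from", "res_to") %in% names(turns)),
            all(turns$res_to >= turns$res_from))
  for (ch in unique(turns$chain)) {
    t <- turns[turns$chain == ch, ]
    t <- t[order(t$res_from), ]
    if (nrow(t) > 1 && any(t$res_from[-1] <= t$res_to[-nrow(t)]))
      stop("overlapping turn ranges in chain ", ch)
  }
  structure(turns, class = c("turn_annotation", "data.frame"))
}

turn_com <- function(traj, frame, ann, id) {
  row <- ann[ann$turn_id == id, ]
  if (nrow(row) == 0) stop("unknown turn id: ", id)
  idx <- which(traj$atoms$chain == row$chain[1] &
                 traj$atoms$resno >= row$res_from[1] &
                 traj$atoms$resno <= row$res_to[1])
  if (length(idx) == 0) stop("turn ", id, " selects no atoms")
  m <- traj$atoms$mass[idx]
  xyz <- matrix(traj$coords[frame, idx, , drop = FALSE][1, , ], ncol = 3)
  colSums(xyz * m) / sum(m)
}

#' Distances between helical-turn centres of mass
#'
#' @param traj A `structure_trajectory`.
#' @param frame Frame index.
#' @param annotation A `turn_annotation`.
#' @param pairs Two-column matrix or data frame of turn-id pairs.
#' @return Named numeric vector of centroid distances (nm); identical pairs
#'   give 0 with a `degenerate` attribute marking the offending entries.
#' @export
turn_com_distances <- function(traj, frame, annotation, pairs) {
  pairs <- as.matrix(pairs)
  out <- numeric(nrow(pairs))
  degen <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    ca <- turn_com(traj, frame, annotation, pairs[k, 1])
    cb <- turn_com(traj, frame, annotation, pairs[k, 2])
    out[k] <- sqrt(sum((ca - cb)^2))
    degen[k] <- identical(pairs[k, 1], pairs[k, 2])
  }
  names(out) <- paste(pairs[, 1], pairs[, 2], sep = "-")
  if (any(degen)) attr(out, "degenerate") <- which(degen)
  out
}

#' First-principal-component template of the transition
#'
#' Pools the frames of all paths, z-scores each feature, and projects onto
#' the first principal component.  The PC1 sign is fixed so the template on
#' average increases from path start to path end (reactive paths run from
#' reactant to product), mirroring the visual convention used when PC1 is
#' read as a transition template.
#'
#' @param fms List of per-path `feature_matrix` objects over the same
#'   features (a single `feature_matrix` is accepted).
#' @return List with `templates` (per-path numeric series), `pooled`
#'   (concatenated template), `var_share` (PC1 fraction of total variance),
#'   `loadings`, and `dropped` (zero-variance feature names).
#' @export
pc1_template <- function(fms) {
  if (inherits(fms, "feature_matrix")) fms <- list(fms)
  pooled <- fm_pool(fms)
  stopifnot(ncol(pooled$values) >= 2, nrow(pooled$values) >= 3)
  sds <- apply(pooled$values, 2, stats::sd)
  dropped <- colnames(pooled$values)[sds == 0]
  if (length(dropped) > 0)
    warning("excluding zero-variance feature(s): ",
            paste(dropped, collapse = ", "))
  keep <- sds > 0
  if (!any(keep)) stop("all features have zero variance")
  z <- scale(pooled$values[, keep, drop = FALSE])
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  proj <- pc$x[, 1]
  path_id <- attr(pooled, "path_id")
  # sign: template should rise with frame order, averaged over paths
  slope <- mean(vapply(split(seq_along(proj), path_id), function(i) {
    stats::cor(proj[i], seq_along(i))
  }, numeric(1)), na.rm = TRUE)
  s <- if (is.na(slope) || slope >= 0) 1 else -1
  proj <- s * proj
  list(templates = split(proj, path_id),
       pooled = as.numeric(proj),
       var_share = pc$sdev[1]^2 / sum(pc$sdev^2),
       loadings = s * pc$rotation[, 1],
       dropped = dropped)
}

#' Select features correlated with a template series
#'
#' Keeps features whose absolute Pearson correlation with the template over
#' the pooled frames exceeds `threshold`; the correlation is recorded in the
#' metadata column `template_r`.  Constant features are dropped with a
#' warning (their correlation is undefined).
#'
#' @param fm A (pooled) `feature_matrix`.
#' @param template Numeric series aligned with the frames of `fm`.
#' @param threshold Absolute-correlation threshold (default 0.25).
#' @return The filtered `feature_matrix`.
#' @export
correlation_select <- function(fm, template, threshold = 0.25) {
  stopifnot(inherits(fm, "feature_matrix"),
            length(template) == nrow(fm$values))
  sds <- apply(fm$values, 2, stats::sd)
  if (any(sds == 0))
    warning("dropping constant feature(s): ",
            paste(colnames(fm$values)[sds == 0], collapse = ", "))
  r <- rep(NA_real_, ncol(fm$values))
  r[sds > 0] <- as.numeric(stats::cor(fm$values[, sds > 0, drop = FALSE],
                                      template))
  keep <- which(!is.na(r) & abs(r) > threshold)
  out <- fm_select(fm, keep)
  out$meta$template_r <- r[keep]
  attr(out, "path_id") <- attr(fm, "path_id")[]
  attr(out, "frame_in_path") <- attr(fm, "frame_in_path")
  out
}
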