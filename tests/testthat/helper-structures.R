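# Toy structures for featurization tests.

# A pentamer of single-atom "residues": 5 chains x n_res residues, with full
# control over every atom position per frame.  positions is a function
# (frame, chain_index 1..5, resno) -> xyz (nm).
make_toy_pentamer <- function(n_frames, n_res = 2, positions) {
  chains <- LETTERS[1:5]
  atoms <- expand.grid(resno = seq_len(n_res), chain = chains,
                       stringsAsFactors = FALSE)
  atoms <- atoms[order(atoms$chain, atoms$resno), ]
  atoms$eleno <- seq_len(nrow(atoms))
  atoms$elety <- "CA"
  atoms$element <- "C"
  coords <- array(NA_real_, c(n_frames, nrow(atoms), 3))
  for (f in seq_len(n_frames))
    for (a in seq_len(nrow(atoms)))
      coords[f, a, ] <- positions(f, match(atoms$chain[a], chains),
                                  atoms$resno[a])
  structure_trajectory(atoms, coords)
}

# default layout: chains on a wide circle (no contacts anywhere)
far_apart <- function(frame, chain, resno) {
  ang <- 2 * pi * (chain - 1) / 5
  c(10 * cos(ang), 10 * sin(ang), resno * 2)
}

# independent brute-force contact enumeration (loops, no shared code with
# stable_contacts): counts instances of each (r_lo, r_hi, offset) class
brute_force_contacts <- function(traj, cutoff, fold = 5L) {
  chains <- sort(unique(traj$atoms$chain))
  n_frames <- dim(traj$coords)[1]
  key_count <- list()
  units <- split(seq_len(nrow(traj$atoms)),
                 paste(traj$atoms$chain, traj$atoms$resno))
  unames <- names(units)
  for (f in seq_len(n_frames)) {
    for (i in seq_along(units)) for (j in seq_along(units)) {
      if (j <= i) next
      di <- Inf
      for (a in units[[i]]) for (b in units[[j]]) {
        if (!traj$atoms$heavy[a] || !traj$atoms$heavy[b]) next
        d <- sqrt(sum((traj$coords[f, a, ] - traj$coords[f, b, ])^2))
        di <- min(di, d)
      }
      if (di >= cutoff) next
      pi_ <- strsplit(unames[i], " ")[[1]]; pj <- strsplit(unames[j], " ")[[1]]
      r1 <- as.integer(pi_[2]); c1 <- match(pi_[1], chains) - 1L
      r2 <- as.integer(pj[2]); c2 <- match(pj[1], chains) - 1L
      if (r1 > r2 || (r1 == r2 && ((c2 - c1) %% fold) > ((c1 - c2) %% fold))) {
        tmp <- r1; r1 <- r2; r2 <- tmp
        tmp <- c1; c1 <- c2; c2 <- tmp
      }
      key <- paste(r1, r2, (c2 - c1) %% fold, sep = "_")
      key_count[[key]] <- (key_count[[key]] %||% 0L) + 1L
    }
  }
  key_count
}

`%||%` <- function(a, b) if (is.null(a)) b else a
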