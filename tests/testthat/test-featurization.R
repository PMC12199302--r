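test_that("minimum residue distance matches exhaustive enumeration", {
  set.seed(1)
  atoms <- data.frame(eleno = 1:5, elety = "CA", element = "C",
                      resno = c(1, 1, 2, 2, 2), chain = "A")
  xyz <- matrix(stats::rnorm(15), 5, 3)
  traj <- structure_trajectory(atoms, xyz)
  d <- min_residue_distance(traj, 1, "A:1", "A:2")
  brute <- min(sapply(1:2, function(i) sapply(3:5, function(j)
    sqrt(sum((xyz[i, ] - xyz[j, ])^2)))))
  expect_equal(as.numeric(d), brute)
  # single-atom residues at a set distance
  atoms2 <- data.frame(eleno = 1:2, elety = "CA", element = "C",
                       resno = 1:2, chain = "A")
  traj2 <- structure_trajectory(atoms2, rbind(c(0, 0, 0), c(0.4, 0, 0)))
  expect_equal(as.numeric(min_residue_distance(traj2, 1, "A:1", "A:2")), 0.4)
  # degenerate self-distance flagged
  d0 <- min_residue_distance(traj2, 1, "A:1", "A:1")
  expect_equal(as.numeric(d0), 0)
  expect_true(attr(d0, "degenerate"))
})

test_that("hydrogens are excluded from heavy-atom distances", {
  atoms <- data.frame(eleno = 1:3, elety = c("CA", "HA", "CA"),
                      element = c("C", "H", "C"),
                      resno = c(1, 1, 2), chain = "A")
  xyz <- rbind(c(0, 0, 0), c(0.35, 0, 0), c(0.5, 0, 0))
  traj <- structure_trajectory(atoms, xyz)
  expect_equal(as.numeric(min_residue_distance(traj, 1, "A:1", "A:2")), 0.5)
  expect_equal(as.numeric(min_residue_distance(traj, 1, "A:1", "A:2",
                                               heavy_only = FALSE)), 0.15)
})

test_that("stable contacts implement symmetry-pooled persistence counting", {
  # contact class (res 1, res 2, offset +1): instance i = (chain i res 1,
  # chain i+1 res 2).  Turn instances on/off individually over 3 frames.
  on <- matrix(TRUE, 3, 5)
  on[1, 1] <- FALSE; on[2, 3] <- FALSE
  on[3, 5] <- FALSE; on[2, 5] <- FALSE   # 11 of 15 instances on
  build <- function(on) make_toy_pentamer(3, n_res = 2,
    positions = function(f, ch, rn) {
      base <- far_apart(f, ch, rn)
      if (rn == 2) {
        donor <- ifelse(ch == 1, 5, ch - 1)       # instance index
        if (on[f, donor]) return(far_apart(f, donor, 1) + c(0.40, 0, 0))
      }
      base
    })
  tr <- build(on)
  sc <- stable_contacts(tr, contact_spec(cutoff = 0.45, persistence = 0.70))
  expect_equal(nrow(sc), 1)
  expect_equal(sc$count, 11)
  expect_equal(sc$fraction, 11 / 15)
  # independent brute-force enumeration agrees
  bf <- brute_force_contacts(tr, 0.45)
  expect_equal(bf[["1_2_1"]], 11L)
  # 10 of 15 falls below the 70% rule
  on[1, 4] <- FALSE
  expect_equal(nrow(stable_contacts(build(on))), 0)
  # full persistence is kept
  expect_equal(stable_contacts(build(matrix(TRUE, 3, 5)))$fraction, 1)
})

test_that("stable contacts refuse fewer chains than the symmetry fold", {
  atoms <- data.frame(eleno = 1:2, elety = "CA", element = "C",
                      resno = 1:2, chain = c("A", "B"))
  traj <- structure_trajectory(atoms, rbind(c(0, 0, 0), c(0.3, 0, 0)))
  expect_error(stable_contacts(traj, contact_spec(symmetry_fold = 5)),
               "chains")
})

test_that("coordination numbers follow the rational switching function", {
  atoms <- data.frame(eleno = 1:2, elety = "CA", element = "C",
                      resno = 1:2, chain = "A")
  at_r <- function(r) structure_trajectory(atoms,
                                           rbind(c(0, 0, 0), c(r, 0, 0)))
  spec <- coordination_spec(r0 = 0.3, exponent = 6)
  expect_equal(coordination_number(at_r(0.3), 1, 1, 2, spec), 0.5)
  expect_equal(coordination_number(at_r(0.6), 1, 1, 2, spec), 1 / 65)
  expect_equal(coordination_number(at_r(1e-9), 1, 1, 2, spec), 1,
               tolerance = 1e-12)
  # continuity: small displacement, small change
  expect_lt(abs(coordination_number(at_r(0.31), 1, 1, 2, spec) -
                  coordination_number(at_r(0.3), 1, 1, 2, spec)), 0.06)
  expect_error(coordination_number(at_r(0.3), 1, integer(), 2, spec))
})

test_that("turn centre-of-mass distances are mass-weighted", {
  atoms <- data.frame(eleno = 1:4, elety = c("CA", "CA", "CA", "N"),
                      element = c("C", "C", "C", "N"),
                      resno = c(1, 2, 5, 6), chain = "A")
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0), c(4, 0, 0))
  traj <- structure_trajectory(atoms, xyz)
  ann <- turn_annotation(data.frame(turn_id = c("t1", "t2"), chain = "A",
                                    res_from = c(1, 5), res_to = c(2, 6)))
  d <- turn_com_distances(traj, 1, ann, cbind("t1", "t2"))
  com1 <- 0.5; com2 <- (3 * 12.011 + 4 * 14.007) / (12.011 + 14.007)
  expect_equal(unname(d), com2 - com1)
  # identical pair flagged
  d0 <- turn_com_distances(traj, 1, ann, cbind("t1", "t1"))
  expect_equal(as.numeric(d0), 0)
  expect_equal(attr(d0, "degenerate"), 1L)
  expect_error(turn_com_distances(traj, 1, ann, cbind("t1", "zz")),
               "unknown turn")
})

test_that("PC1 template captures a shared transition signal", {
  set.seed(2)
  sig <- cumsum(stats::rnorm(300))
  vals <- cbind(a = 2 * sig + 1, b = -3 * sig, c = 0.5 * sig - 4)
  fm <- feature_matrix(seq_len(300), vals,
                       data.frame(name = c("a", "b", "c"),
                                  kind = "synthetic"))
  tp <- pc1_template(list(fm))
  expect_equal(tp$var_share, 1)
  expect_equal(abs(stats::cor(tp$pooled, sig)), 1)
  # two orthogonal equal-variance features split the variance evenly
  set.seed(3)
  v2 <- cbind(a = stats::rnorm(4000), b = stats::rnorm(4000))
  fm2 <- feature_matrix(seq_len(4000), v2,
                        data.frame(name = c("a", "b"), kind = "synthetic"))
  tp2 <- pc1_template(list(fm2))
  expect_equal(tp2$var_share, 0.5, tolerance = 0.05)
  # zero-variance features are excluded with a warning
  v3 <- cbind(a = sig, b = rep(1, 300), c = sig * 2)
  fm3 <- feature_matrix(seq_len(300), v3,
                        data.frame(name = c("a", "b", "c"),
                                   kind = "synthetic"))
  expect_warning(pc1_template(list(fm3)), "zero-variance")
})

test_that("template correlation filter keeps |r| > threshold features", {
  set.seed(4)
  tmpl <- stats::rnorm(10000)
  vals <- cbind(same = tmpl, noise = stats::rnorm(10000),
                anti = -tmpl + stats::rnorm(10000, sd = 0.2))
  fm <- feature_matrix(seq_len(10000), vals,
                       data.frame(name = colnames(vals), kind = "synthetic"))
  kept <- correlation_select(fm, tmpl, threshold = 0.25)
  expect_setequal(kept$meta$name, c("same", "anti"))
  expect_equal(kept$meta$template_r[kept$meta$name == "same"], 1)
  # vacuous threshold keeps everything non-constant
  expect_equal(ncol(correlation_select(fm, tmpl, threshold = 0)$values), 3)
  # constant features are dropped with a warning
  vals2 <- cbind(vals, flat = rep(2, 10000))
  fm2 <- feature_matrix(seq_len(10000), vals2,
                        data.frame(name = colnames(vals2),
                                   kind = "synthetic"))
  expect_warning(correlation_select(fm2, tmpl, 0.25), "constant")
})

test_that("feature scaling round-trips to machine precision", {
  set.seed(5)
  vals <- matrix(stats::rnorm(60, mean = 3, sd = 7), 20, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  fm <- feature_matrix(1:20, vals,
                       data.frame(name = c("a", "b", "c"),
                                  kind = "synthetic"))
  back <- fm_unscale(fm_apply_scaling(fm))
  expect_equal(back$values, fm$values, tolerance = 1e-12)
})

test_that("multi-model PDB files are read as nm-unit trajectories", {
  skip_if_not_installed("bio3d")
  path <- tempfile(fileext = ".pdb")
  line <- function(eleno, name, res, chain, resno, x, y, z, el)
    sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            eleno, name, res, chain, resno, x, y, z, el)
  writeLines(c(
    "MODEL        1",
    line(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
    line(2, "CA", "ALA", "A", 2, 4, 0, 0, "C"),
    "ENDMDL",
    "MODEL        2",
    line(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
    line(2, "CA", "ALA", "A", 2, 5, 0, 0, "C"),
    "ENDMDL",
    "END"), path)
  traj <- read_pdb_trajectory(path)
  expect_equal(dim(traj$coords), c(2, 2, 3))
  expect_equal(as.numeric(min_residue_distance(traj, 1, "A:1", "A:2")), 0.4)
  expect_equal(as.numeric(min_residue_distance(traj, 2, "A:1", "A:2")), 0.5)
})
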