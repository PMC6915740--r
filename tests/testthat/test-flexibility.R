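test_that("multi-model PDB round-trips through write and read", {
  prof <- flex_profile(n_residues = 15, base_amplitude = 0.4)
  tr <- generate_backbone_ensemble(prof, n_frames = 8, seed = 2)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_equal(nrow(back$xyz), 8)
  expect_lt(max(abs(back$xyz - tr$xyz)), 1e-3 + 1e-9)  # PDB precision
  expect_equal(back$atoms$resno, tr$atoms$resno)
  expect_equal(back$atoms$elety, tr$atoms$elety)

  # single model: one frame
  one <- flex_trajectory(tr$atoms, tr$xyz[1, , drop = FALSE])
  f1 <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(one, f1)
  expect_equal(nrow(read_trajectory(f1)$xyz), 1)
})

test_that("XYZ frame files round-trip including inferred residue numbering", {
  prof <- flex_profile(n_residues = 10)
  tr <- generate_backbone_ensemble(prof, n_frames = 5, seed = 3)
  f <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_lt(max(abs(back$xyz - tr$xyz)), 1e-5)
  expect_equal(back$atoms$resno, tr$atoms$resno)
})

test_that("malformed model blocks are rejected with the model index", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1",
               "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
               "ENDMDL",
               "MODEL     2",
               "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
               "ATOM      2  CA  ALA A   2       1.000   0.000   0.000  1.00  0.00",
               "ENDMDL", "END"), f)
  expect_error(read_trajectory(f), "model 2", class = "coldevb_format_error")

  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1", "MODEL     2",
               "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
               "ENDMDL", "ENDMDL"), f2)
  expect_error(read_trajectory(f2), class = "coldevb_format_error")
})

test_that("Kabsch superposition recovers exact rigid transforms", {
  set.seed(5)
  ref <- matrix(rnorm(60, sd = 4), 20, 3)
  fit0 <- kabsch_superpose(ref, ref)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)
  expect_lt(fit0$rmsd, 1e-10)

  rot90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  mob <- sweep(ref %*% rot90, 2, c(3, -1, 5), "+")
  fit <- kabsch_superpose(mob, ref)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_lt(max(abs(fit$coords - ref)), 1e-9)

  line <- cbind(1:10, 2 * (1:10), -(1:10))
  expect_error(kabsch_superpose(line, line + 1),
               class = "coldevb_degeneracy_error")
})

test_that("Kabsch RMSD agrees with an independent superposition oracle", {
  skip_if_not_installed("bio3d")
  set.seed(17)
  ref <- matrix(rnorm(150, sd = 5), 50, 3)
  th <- 0.9
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  mob <- sweep(ref %*% rot, 2, c(1, 2, 3), "+") +
    matrix(rnorm(150, sd = 0.1), 50, 3)
  ours <- kabsch_superpose(mob, ref)
  theirs <- suppressWarnings(
    bio3d::fit.xyz(as.numeric(t(ref)), as.numeric(t(mob))))
  # bio3d::rmsd reports three decimals
  expect_equal(ours$rmsd, bio3d::rmsd(as.numeric(t(ref)), theirs),
               tolerance = 5e-3)
})

test_that("iterative averaging converges to the underlying reference", {
  prof <- flex_profile(n_residues = 12, base_amplitude = 0.3)
  # identical frames: one iteration, average equals the frame
  still <- generate_backbone_ensemble(flex_profile(12, base_amplitude = 0),
                                      n_frames = 3, seed = 1)
  avg0 <- iterative_average(still)
  expect_equal(avg0$iterations, 1)
  expect_equal(avg0$xyz, coldevb:::.frame_mat(still, 1), tolerance = 1e-12)

  # pure noise, no rigid-body motion: average matches the reference up to
  # the (arbitrary) global orientation of the converged average
  tr <- generate_backbone_ensemble(prof, n_frames = 400, seed = 7)
  avg <- iterative_average(tr)
  expect_true(avg$converged)
  aligned <- kabsch_superpose(avg$xyz, prof$xyz_ref)
  err <- max(abs(aligned$coords - prof$xyz_ref))
  expect_lt(err, 3 * 0.3 / sqrt(400) * 4)

  # random rigid-body motion applied to the same displacements: same average
  # up to a global rotation
  set.seed(33)
  moved <- tr$xyz
  for (f in seq_len(nrow(moved))) {
    rot <- coldevb:::.quat_rotation(rnorm(4))
    m <- coldevb:::.frame_mat(tr, f) %*% rot
    moved[f, ] <- coldevb:::.flatten(sweep(m, 2, rnorm(3, sd = 8), "+"))
  }
  avg2 <- iterative_average(flex_trajectory(tr$atoms, moved))
  aligned <- kabsch_superpose(avg2$xyz, avg$xyz)
  expect_lt(aligned$rmsd, 0.02)
})

test_that("RMSF matches its closed form and a brute-force two-pass oracle", {
  prof <- flex_profile(n_residues = 30, base_amplitude = 0.5,
                       loop_multiplier = 1)
  tr <- generate_backbone_ensemble(prof, n_frames = 3000, seed = 12)
  r <- rmsf(tr)
  expect_equal(mean(r), 0.5 * sqrt(3), tolerance = 0.02)

  # static trajectory: all zeros
  still <- generate_backbone_ensemble(flex_profile(10, base_amplitude = 0),
                                      n_frames = 3, seed = 1)
  expect_equal(max(rmsf(still)), 0, tolerance = 1e-12)

  # brute-force two-pass oracle on a small ensemble
  small <- generate_backbone_ensemble(flex_profile(8), n_frames = 10, seed = 4)
  avg <- iterative_average(small)
  got <- rmsf(small, average = avg)
  sup <- matrix(0, 10, ncol(small$xyz))
  for (f in 1:10)
    sup[f, ] <- coldevb:::.flatten(
      kabsch_superpose(coldevb:::.frame_mat(small, f), avg$xyz,
                       backbone_mask(small$atoms))$coords)
  n_at <- nrow(small$atoms)
  brute <- vapply(seq_len(n_at), function(i) {
    cols <- (3 * (i - 1) + 1):(3 * i)
    dev <- sweep(sup[, cols], 2, colMeans(sup[, cols]))
    sqrt(mean(rowSums(dev^2)))
  }, numeric(1))
  expect_equal(got, brute, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("RMSF is invariant under rigid-body transforms of all frames", {
  prof <- flex_profile(n_residues = 20, base_amplitude = 0.4)
  tr <- generate_backbone_ensemble(prof, n_frames = 50, seed = 9)
  r0 <- rmsf(tr)
  th <- 1.1
  rot <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
                3, 3, byrow = TRUE)
  moved <- t(apply(tr$xyz, 1, function(v)
    coldevb:::.flatten(sweep(matrix(v, ncol = 3, byrow = TRUE) %*% rot,
                             2, c(10, -4, 2), "+"))))
  r1 <- rmsf(flex_trajectory(tr$atoms, moved))
  expect_lt(max(abs(r0 - r1)), 1e-9)

  # concatenating identical copies leaves RMSF unchanged
  r2 <- rmsf(flex_trajectory(tr$atoms, rbind(tr$xyz, tr$xyz)))
  expect_lt(max(abs(r0 - r2)), 1e-9)
})

test_that("the equilibration fraction of frames can be discarded", {
  prof <- flex_profile(n_residues = 10, base_amplitude = 0.2)
  tr <- generate_backbone_ensemble(prof, n_frames = 60, seed = 3)
  # corrupt the first sixth with large displacements
  tr$xyz[1:10, ] <- tr$xyz[1:10, ] + matrix(rnorm(10 * ncol(tr$xyz), sd = 5),
                                            10, ncol(tr$xyz))
  full <- rmsf(tr)
  trimmed <- rmsf(tr, discard_fraction = 1 / 6)
  manual <- rmsf(flex_trajectory(tr$atoms, tr$xyz[11:60, ]))
  expect_equal(trimmed, manual, tolerance = 1e-12)
  expect_gt(mean(full), mean(trimmed))
})

test_that("loop reports compute percent change versus the reference", {
  atoms <- flex_profile(n_residues = 20)$atoms
  regions <- data.frame(name = "loopA", first = 5, last = 8)
  bb <- backbone_mask(atoms)
  wt <- rep(1.0, nrow(atoms))
  mut <- rep(1.0, nrow(atoms))
  mut[atoms$resno %in% 5:8] <- 0.83
  rep_out <- loop_report(list(WT = wt, MUT = mut), atoms, regions, "WT")
  expect_equal(rep_out$percent_change[rep_out$variant == "MUT"], -17)
  expect_equal(rep_out$percent_change[rep_out$variant == "WT"], 0)

  # replicate averaging at the RMSF level
  reps <- loop_report(list(WT = list(wt, wt + 0.2), MUT = list(mut, mut)),
                      atoms, regions, "WT")
  expect_equal(reps$rmsf[reps$variant == "WT"], 1.1)
  expect_false(is.na(reps$rmsf_sd[reps$variant == "WT"]))

  expect_error(loop_report(list(WT = wt), atoms,
                           data.frame(name = "far", first = 500, last = 600),
                           "WT"),
               class = "coldevb_config_error")
  expect_error(loop_report(list(MUT = mut), atoms, regions, "WT"),
               class = "coldevb_config_error")
})

test_that("region files parse and validate", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# loop definitions", "name chain first last",
               "Nb3-Nb4 A 60 67", "Cb3-Cb4 A 168 175"), f)
  reg <- read_regions(f)
  expect_equal(nrow(reg), 2)
  expect_equal(reg$first, c(60, 168))
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("name chain first last", "bad A 10 5"), f2)
  expect_error(read_regions(f2), class = "coldevb_format_error")
})
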