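# complex of a 4-atom "protein" frame and a 2-atom "ligand"
complex_traj <- function(frames) {
  atoms <- rbind(
    c("CA", "C", "ALA", "1"), c("CA", "C", "ALA", "2"),
    c("CA", "C", "ALA", "3"), c("CA", "C", "ALA", "4"),
    c("C1", "C", "LIG", "10"), c("C2", "C", "LIG", "10")
  )
  make_traj(atoms, frames)
}

base_complex_frame <- function() {
  rbind(
    c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0), c(0, 3.8, 0),
    c(1.9, 1.9, 2.0), c(1.9, 1.9, 3.4)
  )
}

test_that("ligand RMSD is zero for the reference and under rigid motion", {
  f <- base_complex_frame()
  set.seed(31)
  motion <- random_rigid_motion()
  traj <- complex_traj(list(f, f, apply_rigid(f, motion)))
  series <- ligand_rmsd_series(traj, 5:6, 1:4)
  expect_equal(series, c(0, 0, 0), tolerance = 1e-9)
})

test_that("a pure ligand displacement survives the protein fit", {
  f <- base_complex_frame()
  f2 <- f
  f2[5:6, 1] <- f2[5:6, 1] + 2.0
  traj <- complex_traj(list(f, f2, f2))
  series <- ligand_rmsd_series(traj, 5:6, 1:4)
  expect_equal(series, c(0, 2.0, 2.0), tolerance = 1e-9)
  # hydrogens in the ligand selection are ignored
  expect_error(ligand_rmsd_series(traj, 5:6, 1:2), "at least 3")
})

chain_pair <- function() {
  gen_fluctuating_protein(
    n_frames = 30, quiet_sd = 0, loud_sd = 0, drift = 0,
    n_residues = 8, start_resno = 1, loud_residues = 3:4, seed = 2
  )
}

test_that("per-residue RMSD of a static trajectory is the zero matrix", {
  p <- chain_pair()
  m <- per_residue_rmsd(p$empty, p$empty)
  expect_true(all(m$matrix < 1e-9))
  expect_equal(ncol(m$matrix), 8L)
  expect_length(m$skipped, 0)
})

test_that("a rigidly displaced residue shows up in exactly its column", {
  p <- chain_pair()
  traj <- p$empty
  shifted_frames <- lapply(traj$frames, function(f) {
    idx <- which(traj$topology$resno == 5)
    f[idx, 3] <- f[idx, 3] + 1.0
    f
  })
  shifted <- trajectory(traj$topology, shifted_frames)
  m <- per_residue_rmsd(shifted, traj)
  col5 <- m$matrix[, "5"]
  others <- m$matrix[, colnames(m$matrix) != "5"]
  # the global CA fit redistributes a little of the shift onto other residues
  expect_true(all(col5 > 0.8))
  expect_true(all(others < 0.3))
})

test_that("residues absent from the reference are skipped with a report", {
  p <- chain_pair()
  traj <- p$empty
  ref_top <- traj$topology[traj$topology$resno != 6, ]
  ref <- trajectory(ref_top, list(traj$frames[[1]][traj$topology$resno != 6, ]))
  m <- per_residue_rmsd(traj, ref)
  expect_equal(m$skipped, 6L)
  expect_false("6" %in% colnames(m$matrix))
})

test_that("corrected heatmap: self-comparison cancels exactly and clamps at zero", {
  p <- gen_fluctuating_protein(n_frames = 20, quiet_sd = 0.1, loud_sd = 0.1,
                               drift = 0, n_residues = 8, start_resno = 1,
                               loud_residues = 3:4, seed = 9)
  m <- per_residue_rmsd(p$empty, p$empty)
  hm <- corrected_heatmap(m, m)
  # loaded minus its own per-column mean, clamped: column means must be small
  expect_true(all(colMeans(hm$matrix) < mean(m$matrix)))
  # exact zero when the matrices are constant
  m0 <- m
  m0$matrix[] <- 0.7
  expect_true(all(corrected_heatmap(m0, m0)$matrix == 0))
  # plain arithmetic and clamping
  m_loaded <- m0
  m_loaded$matrix[] <- 1.5
  m_base <- m0
  m_base$matrix[] <- 0.4
  expect_true(all(abs(corrected_heatmap(m_loaded, m_base)$matrix - 1.1) < 1e-12))
  m_big <- m0
  m_big$matrix[] <- 2.0
  expect_true(all(corrected_heatmap(m_loaded, m_big)$matrix == 0))
})

test_that("column mismatches are reported by residue", {
  p <- chain_pair()
  m <- per_residue_rmsd(p$empty, p$empty)
  m2 <- m
  keep <- colnames(m$matrix) != "7"
  m2$matrix <- m2$matrix[, keep]
  expect_error(corrected_heatmap(m, m2), "7")
})

test_that("planted drift on designated residues dominates the corrected map", {
  p <- gen_fluctuating_protein(n_frames = 60, quiet_sd = 0.1, loud_sd = 0.3,
                               loud_residues = 131:136, drift = 1.0, seed = 12)
  loaded <- per_residue_rmsd(p$loaded, p$empty)
  empty_self <- per_residue_rmsd(p$empty, p$empty)
  hm <- corrected_heatmap(loaded, empty_self)
  ranking <- names(sort(colMeans(hm$matrix), decreasing = TRUE))
  expect_setequal(ranking[1:6], as.character(131:136))
})

test_that("loud-regime residues have larger fluctuation columns across seeds", {
  diffs <- vapply(1:20, function(seed) {
    p <- gen_fluctuating_protein(n_frames = 25, quiet_sd = 0.05, loud_sd = 0.2,
                                 drift = 0, n_residues = 10, start_resno = 1,
                                 loud_residues = c(4, 7), seed = seed)
    m <- per_residue_rmsd(p$loaded, p$empty)
    loud_cols <- colnames(m$matrix) %in% c("4", "7")
    mean(colMeans(m$matrix[, loud_cols])) - mean(colMeans(m$matrix[, !loud_cols]))
  }, 0.0)
  expect_true(all(diffs > 0))
  expect_lt(stats::t.test(diffs, alternative = "greater")$p.value, 0.01)
})

test_that("heatmap outputs are invariant under global rigid motion", {
  p <- gen_fluctuating_protein(n_frames = 10, quiet_sd = 0.05, loud_sd = 0.2,
                               drift = 0.5, n_residues = 8, start_resno = 1,
                               loud_residues = 3:4, seed = 3)
  base <- per_residue_rmsd(p$loaded, p$empty)$matrix
  set.seed(77)
  motion <- random_rigid_motion()
  moved <- trajectory(p$loaded$topology,
                      lapply(p$loaded$frames, apply_rigid, motion = motion))
  expect_equal(per_residue_rmsd(moved, p$empty)$matrix, base, tolerance = 1e-9)
})

test_that("mean sidechain RMSD: static zero, known rotation, glycine handling", {
  atoms <- rbind(
    c("N", "N", "SER", "1"), c("CA", "C", "SER", "1"), c("C", "C", "SER", "1"),
    c("O", "O", "SER", "1"), c("CB", "C", "SER", "1"), c("OG", "O", "SER", "1"),
    c("CA", "C", "GLY", "2"), c("CA", "C", "ALA", "3"), c("CB", "C", "ALA", "3")
  )
  f <- rbind(
    c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.2, 0),
    c(2.0, 2.3, 0), c(1.9, -1.4, 0), c(1.6, -2.6, 0.5),
    c(5.3, 0, 0), c(9.1, 0, 0), c(9.5, -1.4, 0.2)
  )
  traj <- make_traj(atoms, list(f, f))
  res <- mean_sidechain_rmsd(traj, residues = c(1, 2, 3))
  expect_equal(res$mean, 0, tolerance = 1e-9)
  expect_equal(res$skipped, 2L)  # glycine has no sidechain heavy atoms

  # displace Ser's sidechain by a known vector in frame 2 and check the oracle
  f2 <- f
  f2[5:6, ] <- sweep(f2[5:6, ], 2, c(0.3, -0.2, 0.6), "+")
  traj2 <- make_traj(atoms, list(f, f2))
  res2 <- mean_sidechain_rmsd(traj2, residues = 1)
  # frame 1 contributes 0; frame 2's displacement is partially absorbed by
  # the (unchanged) CA fit, so compute the oracle through the same fit
  fit <- kabsch_superpose(f2[c(2, 7, 8), ], f[c(2, 7, 8), ])
  oracle <- rmsd(apply_superposition(f2[5:6, ], fit), f[5:6, ])
  expect_equal(res2$mean, mean(c(0, oracle)), tolerance = 1e-9)

  expect_warning(res3 <- mean_sidechain_rmsd(traj, residues = 2), "nothing to average")
  expect_true(is.na(res3$mean))
})
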