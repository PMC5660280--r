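triple_frame <- function(D, H, A) rbind(D, H, A)

test_that("the geometric hydrogen-bond gate applies both criteria", {
  tr <- hbond_triple(1, 2, 3)
  crit <- hbond_criteria()
  # collinear, short: bonded
  expect_true(is_hbonded(triple_frame(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2.9)), tr, crit))
  # H-A distance exactly 3.0 (not < 3.0) and 71.6 deg deviation: not bonded
  expect_false(is_hbonded(triple_frame(c(0, 0, 0), c(0, 0, 1), c(0, 3.0, 1.0)), tr, crit))
  # short but bent beyond 35 deg: not bonded
  deg <- pi / 180
  A <- c(0, 0, 1) + 2.0 * c(sin(40 * deg), 0, cos(40 * deg))
  # deviation at the donor for this A is ~27 deg; build one that exceeds 35 at the donor
  A2 <- c(2.0 * sin(80 * deg), 0, 1 + 2.0 * cos(80 * deg))
  dev2 <- vec_angle(c(0, 0, 1), c(0, 0, 0), A2)
  expect_gt(dev2, 35)
  expect_false(is_hbonded(triple_frame(c(0, 0, 0), c(0, 0, 1), A2), tr, crit))
  expect_error(is_hbonded(triple_frame(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2)),
                          hbond_triple(1, 2, 9), crit), "out of range")
})

test_that("the acceptor-vertex angle convention is available", {
  tr <- hbond_triple(1, 2, 3)
  D <- c(0, 0, 0); H <- c(0, 0, 1)
  A <- c(2.0 * sin(30 * pi / 180), 0, 1 + 2.0 * cos(30 * pi / 180))
  donor_dev <- vec_angle(H, D, A)
  acceptor_dev <- vec_angle(D, A, H)
  expect_false(isTRUE(all.equal(donor_dev, acceptor_dev)))
  f <- triple_frame(D, H, A)
  crit_d <- hbond_criteria(max_deviation_angle = donor_dev + 1, angle_vertex = "donor")
  crit_d2 <- hbond_criteria(max_deviation_angle = donor_dev - 1, angle_vertex = "donor")
  expect_true(is_hbonded(f, tr, crit_d))
  expect_false(is_hbonded(f, tr, crit_d2))
  crit_a <- hbond_criteria(max_deviation_angle = acceptor_dev + 1, angle_vertex = "acceptor")
  expect_true(is_hbonded(f, tr, crit_a))
})

test_that("occupancy equals brute-force per-frame evaluation and is exact for the generator", {
  s <- gen_hbond(n_frames = 100, occupancy = 0.6, mode = "deterministic", seed = 4)
  tr <- hbond_triple(1, 2, 3)
  st <- hbond_occupancy(s$trajectory, tr)
  expect_equal(st$occupancy, 60.0)
  brute <- mean(vapply(s$trajectory$frames, is_hbonded, TRUE,
                       triple = tr, criteria = hbond_criteria())) * 100
  expect_identical(st$occupancy, brute)
  expect_equal(which(st$bonded), s$ground_truth$bonded_frames)
  # boundary occupancies
  expect_equal(hbond_occupancy(gen_hbond(50, 1, seed = 1)$trajectory, tr)$occupancy, 100)
  tight <- hbond_criteria(max_ha_distance = 0.1)
  expect_equal(hbond_occupancy(s$trajectory, tr, tight)$occupancy, 0)
})

test_that("mean distance averages over all frames, bonded or not", {
  s <- gen_hbond(n_frames = 10, occupancy = 0.5, mode = "deterministic", seed = 1)
  st <- hbond_occupancy(s$trajectory, hbond_triple(1, 2, 3))
  expect_equal(st$mean_distance, (2.0 + 4.0) / 2, tolerance = 1e-9)
})

test_that("occupancy is monotone in both criteria thresholds", {
  s <- gen_hbond(n_frames = 200, occupancy = 0.5, mode = "bernoulli", seed = 17)
  tr <- hbond_triple(1, 2, 3)
  occ_d <- vapply(c(1.5, 2.5, 3.5, 4.5), function(d) {
    hbond_occupancy(s$trajectory, tr, hbond_criteria(max_ha_distance = d))$occupancy
  }, 0.0)
  expect_true(all(diff(occ_d) >= 0))
  occ_a <- vapply(c(10, 35, 65, 90), function(a) {
    hbond_occupancy(s$trajectory, tr, hbond_criteria(max_deviation_angle = a))$occupancy
  }, 0.0)
  expect_true(all(diff(occ_a) >= 0))
})

test_that("a multi-acceptor triple uses the closest acceptor per frame", {
  # two candidate acceptors trading places across frames
  atoms <- rbind(
    c("N", "N", "DON", "1"), c("H", "H", "DON", "1"),
    c("O1", "O", "ACC", "2"), c("O2", "O", "ACC", "2")
  )
  f1 <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 3.0), c(0, 0, 6))
  f2 <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 6), c(0, 0, 3.5))
  traj <- make_traj(atoms, list(f1, f2))
  st <- hbond_occupancy(traj, hbond_triple(1, 2, c(3, 4)))
  expect_equal(st$distances, c(2.0, 2.5))
})

test_that("distance series tracks the closest pair and is symmetric", {
  atoms <- rbind(
    c("C1", "C", "GRA", "1"),
    c("O1", "O", "GRB", "2"), c("O2", "O", "GRB", "2"), c("O3", "O", "GRB", "2")
  )
  f1 <- rbind(c(0, 0, 0), c(2.29, 0, 0), c(5, 0, 0), c(9, 0, 0))
  traj1 <- make_traj(atoms, list(f1))
  expect_equal(distance_series(traj1, 1L, 2:4)$series, 2.29)
  f2 <- rbind(c(0, 0, 0), c(2, 0, 0), c(5, 0, 0), c(9, 0, 0))
  f3 <- rbind(c(0, 0, 0), c(7, 0, 0), c(4, 0, 0), c(9, 0, 0))
  traj2 <- make_traj(atoms, list(f2, f3))
  ds <- distance_series(traj2, 1L, 2:4)
  expect_equal(ds$series, c(2, 4))  # closest atom switches from O1 to O2
  expect_equal(ds$mean, 3.0)
  # brute-force pairwise scan
  brute <- vapply(traj2$frames, function(f) {
    min(apply(f[2:4, , drop = FALSE], 1, function(p) vec_distance(f[1, ], p)))
  }, 0.0)
  expect_equal(ds$series, brute)
  ds_rev <- distance_series(traj2, 2:4, 1L)
  expect_equal(ds$series, ds_rev$series)
  expect_error(distance_series(traj2, integer(0), 2:4), "empty selection")
})

hexagon <- function(offset = c(0, 0, 0), rot = diag(3)) {
  ang <- (0:5) * pi / 3
  sweep(cbind(1.39 * cos(ang), 1.39 * sin(ang), 0) %*% t(rot), 2, offset, "+")
}

test_that("stacking classification separates the three geometries", {
  rot_x90 <- matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE)
  par_frame <- rbind(hexagon(), hexagon(offset = c(1.5, 0, 3.5)))
  expect_equal(as.character(classify_stacking(par_frame, 1:6, 7:12)),
               "parallel_displaced")
  t_frame <- rbind(hexagon(), hexagon(offset = c(0, 0, 5), rot = rot_x90))
  expect_equal(as.character(classify_stacking(t_frame, 1:6, 7:12)), "t_shaped")
  far_frame <- rbind(hexagon(), hexagon(offset = c(0, 0, 9)))
  expect_equal(as.character(classify_stacking(far_frame, 1:6, 7:12)), "unclassified")
  expect_error(classify_stacking(rbind(hexagon(), hexagon() + matrix(rnorm(18, sd = 1), 6, 3)),
                                 1:6, 7:12), "not planar")
  expect_error(classify_stacking(par_frame, 1:2, 7:12), "at least 3")
})

test_that("stacking class is invariant under rigid motion of the frame", {
  s <- gen_stacked_rings("parallel_displaced", seed = 5)
  f <- s$trajectory$frames[[1]]
  base <- as.character(classify_stacking(f, 1:6, 7:12))
  set.seed(10)
  for (rep in 1:5) {
    motion <- random_rigid_motion()
    expect_equal(as.character(classify_stacking(apply_rigid(f, motion), 1:6, 7:12)),
                 base)
  }
})

test_that("stacking fractions aggregate per-frame classes", {
  rot_x90 <- matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE)
  f_par <- rbind(hexagon(), hexagon(offset = c(1.5, 0, 3.5)))
  f_t <- rbind(hexagon(), hexagon(offset = c(0, 0, 5), rot = rot_x90))
  atoms <- cbind(paste0("C", rep(1:6, 2)), "C",
                 rep(c("RGA", "RGB"), each = 6), rep(c("1", "2"), each = 6))
  traj <- make_traj(atoms, list(f_par, f_t))
  fr <- stacking_fractions(traj, 1:6, 7:12)
  expect_equal(unname(fr[c("parallel_displaced", "t_shaped")]), c(0.5, 0.5))
})
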