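# trajectory with an ion at the origin and partner shells at fixed radii
shell_traj <- function(radii_per_frame) {
  n <- max(vapply(radii_per_frame, length, 0L))
  frames <- lapply(radii_per_frame, function(radii) {
    coords <- matrix(0, 1 + n, 3)
    dirs <- diag(3)[rep(1:3, length.out = length(radii)), , drop = FALSE]
    signs <- rep(c(1, -1), length.out = length(radii))
    for (i in seq_along(radii)) {
      coords[1 + i, ] <- dirs[i, ] * radii[i] * signs[i] +
        c(0, 0, 0.001 * i)  # break exact coincidence
    }
    if (length(radii) < n) {
      coords[(2 + length(radii)):(1 + n), ] <- 50  # park unused atoms far away
    }
    coords
  })
  atoms <- rbind(
    c("ZN", "Zn", "ZN", "1"),
    cbind(paste0("O", seq_len(n)), "O", "LIG", "2")
  )
  make_traj(atoms, frames)
}

test_that("the RDF number integral counts partners per shell", {
  traj <- shell_traj(list(c(rep(2.0, 5), rep(4.0, 3))))
  prof <- compute_rdf(traj, 1L, 2:9, bin_width = 0.1, r_max = 5)
  expect_equal(rdf_number_at(prof, 2.83), 5)
  expect_equal(rdf_number_at(prof, 5.0), 8)
  expect_true(all(diff(prof$number_integral) >= 0))
})

test_that("the integral averages over frames", {
  traj <- shell_traj(list(rep(2.0, 5), rep(2.0, 6)))
  prof <- compute_rdf(traj, 1L, 2:7, bin_width = 0.1, r_max = 5)
  expect_equal(rdf_number_at(prof, 2.83), 5.5)
})

test_that("an empty partner selection gives an all-zero profile", {
  traj <- shell_traj(list(rep(2.0, 3)))
  prof <- compute_rdf(traj, 1L, integer(0))
  expect_true(all(prof$density == 0))
  expect_true(all(prof$number_integral == 0))
})

test_that("a multi-atom center selection is refused", {
  traj <- shell_traj(list(rep(2.0, 3)))
  expect_error(compute_rdf(traj, 1:2, 3:4), "exactly 1 atom")
})

make_profile <- function(density, bin_width = 0.1) {
  edges <- seq(0, length(density) * bin_width, by = bin_width)
  structure(
    list(bin_edges = edges, bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
         density = density, number_integral = cumsum(density),
         n_frames = 1L, r_max = max(edges)),
    class = "RDFProfile"
  )
}

test_that("first minimum: raw scan finds the first zero bin between two peaks", {
  # peaks around 2.0 and 3.9; zero density on [2.5, 3.0)
  dens <- numeric(50)
  dens[16:25] <- c(1, 2, 4, 6, 8, 6, 4, 2, 1, 0.5)   # 1.55 .. 2.45
  dens[31:44] <- c(0.5, 1, 2, 3, 5, 7, 8, 9, 8, 7, 5, 3, 2, 1)  # 3.05 .. 4.35
  prof <- make_profile(dens)
  expect_equal(detect_first_minimum(prof, smooth = FALSE), 2.55)
})

test_that("first minimum: plateau ties return the smaller radius", {
  dens <- c(0, 1, 5, 2, 2, 6, 1, 0, 0, 0)
  prof <- make_profile(dens)
  expect_equal(detect_first_minimum(prof, smooth = FALSE), prof$bin_mid[4])
})

test_that("first minimum: monotone tails are a detection error", {
  dens <- c(0, 1, 8, 4, 2, 1, 0.5, 0.2, 0.1, 0)
  expect_error(detect_first_minimum(make_profile(dens), smooth = FALSE),
               "no interior minimum|no rise")
})

test_that("smoothing suppresses a one-bin shot-noise dip", {
  # a shallow one-bin dip in the descending flank must not become the minimum
  dens <- c(0, 2, 6, 9, 8, 7, 5.4, 6, 5, 4, 3, 2, 1, 0.5, 0.2, 0, 0, 1, 4, 7,
            4, 1, 0, 0)
  prof <- make_profile(dens)
  raw <- detect_first_minimum(prof, smooth = FALSE)
  smoothed <- detect_first_minimum(prof, smooth = TRUE)
  expect_equal(raw, prof$bin_mid[7])       # fooled by the dip
  expect_equal(smoothed, prof$bin_mid[16]) # real inter-peak valley
})

test_that("coordination series recovers the generated coordination number", {
  s <- gen_zn_site(n_frames = 100, n_coordinating = 5, bond_length = 2.0,
                   noise_sd = 0.05, seed = 7)
  cn <- coordination_series(s$trajectory, list(resname = "ZN"),
                            s$ground_truth$partner_indices, cutoff = 2.83)
  expect_equal(cn$mean_cn, 5.0)
  expect_equal(cn$per_frame_cn, s$ground_truth$per_frame_counts)
  expect_equal(cn$peak_position, 2.0, tolerance = 0.1)
  # cutoff below every distance
  cn0 <- coordination_series(s$trajectory, list(resname = "ZN"),
                             s$ground_truth$partner_indices, cutoff = 1.0)
  expect_equal(cn0$mean_cn, 0)
})

test_that("a flickering partner adds its bound fraction to the mean CN", {
  s <- gen_zn_site(n_frames = 100, n_coordinating = 5, flicker_fraction = 0.4,
                   seed = 21)
  cn <- coordination_series(s$trajectory, list(resname = "ZN"),
                            s$ground_truth$partner_indices, cutoff = 2.83)
  expect_equal(cn$mean_cn, 5.4)
  expect_equal(s$ground_truth$true_cn, 5.4)
})

test_that("denticity classifies bidentate / monodentate / unbound frames", {
  both <- shell_traj(list(c(2.0, 2.0)))
  expect_equal(
    denticity_fractions(both, 1L, 2:3, cutoff = 2.83),
    c(bidentate = 1, monodentate = 0, unbound = 0)
  )
  one <- shell_traj(list(c(2.0, 4.0)))
  expect_equal(
    denticity_fractions(one, 1L, 2:3, cutoff = 2.83)[["monodentate"]], 1
  )
  alternating <- shell_traj(list(c(2.0, 2.0), c(2.0, 4.0)))
  fr <- denticity_fractions(alternating, 1L, 2:3, cutoff = 2.83)
  expect_equal(unname(fr[c("bidentate", "monodentate")]), c(0.5, 0.5))
  expect_equal(sum(fr), 1)
  expect_error(denticity_fractions(both, 1L, 2L, cutoff = 2.83), "exactly 2")
})

test_that("mean_count_within counts rare visitors and agrees with the RDF", {
  radii <- c(rep(list(numeric(0)), 97), rep(list(4.5), 3))
  traj <- shell_traj(radii)
  partners <- 2L
  expect_equal(mean_count_within(traj, 1L, partners, 5), 0.03)
  expect_equal(mean_count_within(traj, 1L, partners, 0), 0)
  prof <- compute_rdf(traj, 1L, partners, bin_width = 0.05, r_max = 10)
  for (r in c(1, 3.3, 5, 7.7)) {
    expect_equal(mean_count_within(traj, 1L, partners, r),
                 rdf_number_at(prof, r), tolerance = 1e-12)
  }
})

test_that("mean_count_within is non-decreasing in the radius", {
  s <- gen_zn_site(n_frames = 20, seed = 5)
  radii <- seq(0.5, 9.5, by = 0.5)
  counts <- vapply(radii, function(r) {
    mean_count_within(s$trajectory, list(resname = "ZN"),
                      select_atoms(s$trajectory, element = c("O", "N")), r)
  }, 0.0)
  expect_true(all(diff(counts) >= 0))
})

test_that("density grows as r^2 for uniform positions in a ball", {
  set.seed(123)
  n <- 10000
  # uniform in a ball of radius 8 by radius inversion
  u <- runif(n)
  r <- 8 * u^(1 / 3)
  dirs <- matrix(rnorm(3 * n), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  coords <- rbind(c(0, 0, 0), dirs * r)
  atoms <- rbind(c("ZN", "Zn", "ZN", "1"),
                 cbind(paste0("O", 1:n), "O", "HOH", as.character(1 + seq_len(n))))
  traj <- make_traj(atoms, list(coords))
  prof <- compute_rdf(traj, 1L, 1L + seq_len(n), bin_width = 0.5, r_max = 8)
  counts <- prof$density
  edges <- prof$bin_edges
  expected <- n * (edges[-1]^3 - edges[-length(edges)]^3) / 8^3
  chisq <- sum((counts - expected)^2 / expected)
  p <- stats::pchisq(chisq, df = length(counts) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})
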