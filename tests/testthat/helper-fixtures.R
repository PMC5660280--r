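# In-code fixtures shared across the suite.

# Minimal trajectory built directly from a topology table and coordinate
# frames; each row of `atoms` is c(name, element, resname, resno).
make_traj <- function(atoms, frames) {
  top <- data.frame(
    serial = seq_len(nrow(atoms)),
    name = atoms[, 1], element = atoms[, 2],
    resname = atoms[, 3], resno = as.integer(atoms[, 4]),
    chain = "A", stringsAsFactors = FALSE
  )
  trajectory(top, frames)
}

# Hand-written two-model, three-atom PDB text (Zn ion + Glu carboxylate O).
fixture_pdb_lines <- function() {
  c(
    "MODEL        1",
    "ATOM      1 ZN   ZN  A   1       0.000   0.000   0.000  1.00  0.00          ZN",
    "ATOM      2  OE1 GLU A 177       2.000   0.000   0.000  1.00  0.00",
    "ATOM      3  OE2 GLU A 177       0.000   2.100   0.000  1.00  0.00",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1 ZN   ZN  A   1       0.000   0.000   0.100  1.00  0.00          ZN",
    "ATOM      2  OE1 GLU A 177       2.050   0.000   0.000  1.00  0.00",
    "ATOM      3  OE2 GLU A 177       0.000   2.150   0.000  1.00  0.00",
    "ENDMDL",
    "END"
  )
}

write_fixture_pdb <- function(lines = fixture_pdb_lines()) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

# A random rigid motion (proper rotation + translation), seeded by caller.
random_rigid_motion <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 5))
}

apply_rigid <- function(coords, motion) {
  sweep(coords %*% t(motion$R), 2, motion$t, "+")
}

# Independent RMSD oracle: coarse Euler-angle grid plus Nelder-Mead
# refinement; never uses the SVD path under test.
brute_force_min_rmsd <- function(mobile, reference, grid_step = 30) {
  euler_rot <- function(a, b, c) {
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  obj <- function(ang) {
    R <- euler_rot(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  grid <- seq(0, 2 * pi, by = grid_step * pi / 180)
  best <- Inf
  best_ang <- c(0, 0, 0)
  for (a in grid) for (b in seq(0, pi, by = grid_step * pi / 180)) for (cc in grid) {
    v <- obj(c(a, b, cc))
    if (v < best) {
      best <- v
      best_ang <- c(a, b, cc)
    }
  }
  opt <- stats::optim(best_ang, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}
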