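# Run expr with a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.unit_directions <- function(n) {
  # isotropic unit vectors
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

.make_topology <- function(serial, name, element, resname, resno, chain = "A") {
  data.frame(
    serial = serial, name = name, element = element,
    resname = resname, resno = as.integer(resno), chain = chain,
    stringsAsFactors = FALSE
  )
}

#' Synthetic Zn(II) coordination-site trajectory
#'
#' A central Zn(II) ion at the origin coordinated by `n_coordinating` O/N
#' partner atoms placed at `bond_length` along fixed random directions, with
#' isotropic Gaussian positional noise per frame; a shell of `n_shell_waters`
#' water oxygens is placed between 6 and 9 Angstrom. Optionally one extra
#' partner "flickers": it sits at `bond_length` in exactly
#' `floor(flicker_fraction * n_frames)` frames (the first ones) and at
#' `cutoff + 1` Angstrom otherwise, so the expected coordination number is
#' `n_coordinating + flicker_fraction` by construction. Parameters that
#' would let noise carry a bound partner across the cutoff
#' (`noise_sd > (cutoff - bond_length)/4`) are refused.
#'
#' @param n_frames number of frames (default 100).
#' @param n_coordinating number of bound O/N partners (default 5).
#' @param bond_length ion-partner distance, Angstrom (default 2.0; a typical
#'   Zn-O/N first-shell distance is 2.0-2.1).
#' @param noise_sd isotropic positional noise SD per coordinate, Angstrom
#'   (default 0.05).
#' @param n_shell_waters water oxygens in the 6-9 Angstrom shell (default 10).
#' @param seed RNG seed.
#' @param cutoff analysis cutoff recorded in the ground truth (default 2.83).
#' @param flicker_fraction fraction of frames in which the extra partner is
#'   bound (default 0 = no extra partner).
#' @return list with `trajectory` and `ground_truth` (true CN, per-frame
#'   within-cutoff counts, partner indices, cutoff).
#' @export
gen_zn_site <- function(n_frames = 100, n_coordinating = 5, bond_length = 2.0,
                        noise_sd = 0.05, n_shell_waters = 10, seed = 1,
                        cutoff = 2.83, flicker_fraction = 0) {
  stopifnot(n_coordinating >= 0, noise_sd >= 0, n_frames >= 1,
            flicker_fraction >= 0, flicker_fraction <= 1)
  if (bond_length >= cutoff) stop("bond_length must lie below the cutoff")
  if (noise_sd > (cutoff - bond_length) / 4) {
    stop("noise_sd too large: partners could cross the cutoff (requires noise_sd <= (cutoff - bond_length)/4)")
  }
  .with_seed(seed, {
    has_flicker <- flicker_fraction > 0
    n_part <- n_coordinating + as.integer(has_flicker)
    dirs <- if (n_part) .unit_directions(n_part) else matrix(0, 0, 3)
    wdirs <- if (n_shell_waters) .unit_directions(n_shell_waters) else matrix(0, 0, 3)
    wrad <- if (n_shell_waters) stats::runif(n_shell_waters, 6, 9) else numeric(0)

    n_atoms <- 1L + n_part + n_shell_waters
    elements <- c("Zn",
                  if (n_part) rep(c("O", "N"), length.out = n_part),
                  rep("O", n_shell_waters))
    names_ <- c("ZN",
                if (n_part) paste0(rep(c("O", "N"), length.out = n_part),
                                   seq_len(n_part)),
                rep("OW", n_shell_waters))
    resname <- c("ZN", rep("LIG", n_part), rep("HOH", n_shell_waters))
    resno <- c(1L, rep(2L, n_part),
               if (n_shell_waters) 2L + seq_len(n_shell_waters) else integer(0))
    top <- .make_topology(seq_len(n_atoms), names_, elements, resname, resno)

    n_bonded_flicker <- if (has_flicker) floor(flicker_fraction * n_frames) else 0L
    frames <- vector("list", n_frames)
    counts <- integer(n_frames)
    for (f in seq_len(n_frames)) {
      coords <- matrix(0, nrow = n_atoms, ncol = 3)
      if (n_part) {
        base <- dirs * bond_length
        if (has_flicker && f > n_bonded_flicker) {
          base[n_part, ] <- dirs[n_part, ] * (cutoff + 1)
        }
        coords[1L + seq_len(n_part), ] <-
          base + matrix(stats::rnorm(3 * n_part, sd = noise_sd), ncol = 3)
      }
      if (n_shell_waters) {
        coords[1L + n_part + seq_len(n_shell_waters), ] <-
          wdirs * wrad + matrix(stats::rnorm(3 * n_shell_waters, sd = noise_sd), ncol = 3)
      }
      frames[[f]] <- coords
      d <- sqrt(rowSums(coords[-1L, , drop = FALSE]^2))
      counts[f] <- sum(d[seq_len(n_part)] < cutoff + 1e-9)
    }
    list(
      trajectory = trajectory(top, frames),
      ground_truth = list(
        scenario = "zn_site",
        true_cn = n_coordinating + if (has_flicker) n_bonded_flicker / n_frames else 0,
        per_frame_counts = counts,
        partner_indices = if (n_part) 1L + seq_len(n_part) else integer(0),
        water_o_indices = if (n_shell_waters) 1L + n_part + seq_len(n_shell_waters) else integer(0),
        cutoff = cutoff,
        bond_length = bond_length,
        seed = seed
      )
    )
  })
}

#' Synthetic donor-hydrogen-acceptor trajectory with known occupancy
#'
#' In bonded frames the triple satisfies comfortable hydrogen-bond geometry
#' (H-acceptor 2.0 Angstrom, 5 degree deviation); in unbonded frames it
#' violates both criteria (4.0 Angstrom, 60 degrees). Deterministic mode
#' bonds exactly `floor(occupancy * n_frames)` frames (the first ones), so
#' measured occupancy is exact, not statistical; Bernoulli mode draws each
#' frame independently with probability `occupancy`.
#'
#' @param n_frames number of frames.
#' @param occupancy target bonded fraction in `[0, 1]`.
#' @param mode `"deterministic"` or `"bernoulli"`.
#' @param seed RNG seed (used by Bernoulli mode; kept for API symmetry
#'   otherwise).
#' @return list with `trajectory`, `ground_truth` (bonded frame index set,
#'   occupancy fraction, triple indices).
#' @export
gen_hbond <- function(n_frames = 100, occupancy = 0.6,
                      mode = c("deterministic", "bernoulli"), seed = 1) {
  stopifnot(occupancy >= 0, occupancy <= 1, n_frames >= 1)
  mode <- match.arg(mode)
  .with_seed(seed, {
    top <- .make_topology(
      1:3, c("N", "H", "O"), c("N", "H", "O"),
      c("DON", "DON", "ACC"), c(1L, 1L, 2L)
    )
    bonded <- if (mode == "deterministic") {
      seq_len(n_frames) <= floor(occupancy * n_frames)
    } else {
      stats::runif(n_frames) < occupancy
    }
    deg <- pi / 180
    acc_bonded <- c(2.0 * sin(5 * deg), 0, 1 + 2.0 * cos(5 * deg))
    acc_unbonded <- c(4.0 * sin(60 * deg), 0, 1 + 4.0 * cos(60 * deg))
    frames <- lapply(seq_len(n_frames), function(f) {
      rbind(c(0, 0, 0), c(0, 0, 1), if (bonded[f]) acc_bonded else acc_unbonded)
    })
    list(
      trajectory = trajectory(top, frames),
      ground_truth = list(
        scenario = "hbond",
        occupancy = sum(bonded) / n_frames,
        requested_occupancy = occupancy,
        bonded_frames = which(bonded),
        donor = 1L, hydrogen = 2L, acceptor = 3L,
        mode = mode, seed = seed
      )
    )
  })
}

#' Synthetic apo/loaded protein pair with two fluctuation regimes
#'
#' A toy chain of pseudo-residues (CA + CB per residue, 3.8 Angstrom CA
#' spacing) numbered from `start_resno`. The "empty" (apo) trajectory
#' fluctuates with `quiet_sd` everywhere; the "loaded" trajectory fluctuates
#' with `loud_sd` on `loud_residues` and additionally displaces them by a
#' fixed `drift` offset, emulating a lid segment that moves when the ligand
#' is bound. Frame 1 of the empty trajectory is noise-free, so it can serve
#' directly as the apo reference structure.
#'
#' @param n_frames frames per trajectory (default 200).
#' @param quiet_sd baseline per-coordinate fluctuation SD, Angstrom
#'   (default 0.1).
#' @param loud_sd fluctuation SD of `loud_residues` in the loaded system,
#'   Angstrom (default 0.3; must be >= `quiet_sd`).
#' @param loud_residues residue numbers with the loud regime (default
#'   131:136, a six-residue lid segment).
#' @param drift fixed displacement of `loud_residues` in the loaded system,
#'   Angstrom (default 1.0).
#' @param n_residues chain length (default 31).
#' @param start_resno first residue number (default 120).
#' @param seed RNG seed.
#' @return list with `empty`, `loaded` (Trajectories) and `ground_truth`
#'   (loud residues, drift, SDs, expected corrected-heatmap dominance).
#' @export
gen_fluctuating_protein <- function(n_frames = 200, quiet_sd = 0.1, loud_sd = 0.3,
                                    loud_residues = 131:136, drift = 1.0,
                                    n_residues = 31, start_resno = 120, seed = 1) {
  stopifnot(loud_sd >= quiet_sd, quiet_sd >= 0, n_frames >= 2)
  resnos <- start_resno + seq_len(n_residues) - 1L
  if (!all(loud_residues %in% resnos)) {
    stop("loud_residues outside the generated chain (",
         min(resnos), "-", max(resnos), ")")
  }
  .with_seed(seed, {
    # helical backbone (~3.8 A CA-CA, ~100 deg turn) with CB pointing outward;
    # a straight chain would leave the global fit rotationally degenerate
    n_atoms <- 2L * n_residues
    base <- matrix(0, n_atoms, 3)
    for (i in seq_len(n_residues)) {
      phi <- i * 100 * pi / 180
      radial <- c(cos(phi), sin(phi), 0)
      ca <- c(2.3 * radial[1:2], 1.5 * i)
      base[2L * i - 1L, ] <- ca
      base[2L * i, ] <- ca + 1.5 * radial
    }
    top <- .make_topology(
      seq_len(n_atoms),
      rep(c("CA", "CB"), n_residues),
      rep("C", n_atoms),
      rep("ALA", n_atoms),
      rep(resnos, each = 2L)
    )
    loud_atoms <- which(top$resno %in% loud_residues)
    drift_dir <- c(0, 0, 1)

    make_frames <- function(loaded) {
      lapply(seq_len(n_frames), function(f) {
        sd_per_atom <- rep(quiet_sd, n_atoms)
        coords <- base
        if (loaded) {
          sd_per_atom[loud_atoms] <- loud_sd
          coords[loud_atoms, ] <- coords[loud_atoms, ] +
            matrix(drift * drift_dir, nrow = length(loud_atoms), ncol = 3, byrow = TRUE)
        }
        noise <- matrix(stats::rnorm(3 * n_atoms), ncol = 3) * sd_per_atom
        if (!loaded && f == 1L) noise[] <- 0  # clean apo reference frame
        coords + noise
      })
    }
    empty <- trajectory(top, make_frames(FALSE))
    loaded <- trajectory(top, make_frames(TRUE))
    list(
      empty = empty,
      loaded = loaded,
      ground_truth = list(
        scenario = "fluctuating_protein",
        loud_residues = loud_residues,
        drift = drift, quiet_sd = quiet_sd, loud_sd = loud_sd,
        residues = resnos, seed = seed
      )
    )
  })
}

#' Synthetic stacked aromatic ring pair
#'
#' Two ideal benzene-like hexagons (1.39 Angstrom edges). Parallel-displaced:
#' parallel ring planes, centroid offset (1.5, 0, 3.5) Angstrom. T-shaped:
#' perpendicular planes, centroids 5.0 Angstrom apart. Gaussian jitter is
#' added per atom.
#'
#' @param class `"parallel_displaced"` or `"t_shaped"`.
#' @param seed RNG seed.
#' @param jitter per-coordinate Gaussian jitter SD, Angstrom (default 0.02).
#' @return list with `trajectory` (1 frame), ring index sets in
#'   `ground_truth` along with the requested class.
#' @export
gen_stacked_rings <- function(class = c("parallel_displaced", "t_shaped"),
                              seed = 1, jitter = 0.02) {
  class <- match.arg(class)
  .with_seed(seed, {
    ang <- (0:5) * pi / 3
    hex <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
    ring_a <- hex
    ring_b <- if (class == "parallel_displaced") {
      sweep(hex, 2, c(1.5, 0, 3.5), "+")
    } else {
      # rotate the plane 90 degrees about x (normal z -> y), centroid at 5 A
      rot <- matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE)
      sweep(hex %*% t(rot), 2, c(0, 0, 5.0), "+")
    }
    coords <- rbind(ring_a, ring_b)
    if (jitter > 0) coords <- coords + matrix(stats::rnorm(36, sd = jitter), ncol = 3)
    top <- .make_topology(
      1:12, paste0("C", rep(1:6, 2)), rep("C", 12),
      rep(c("RGA", "RGB"), each = 6), rep(c(1L, 2L), each = 6)
    )
    list(
      trajectory = trajectory(top, list(coords)),
      ground_truth = list(
        scenario = "stacked_rings", class = class,
        ring_a = 1:6, ring_b = 7:12, jitter = jitter, seed = seed
      )
    )
  })
}

#' Write a generated scenario to disk
#'
#' Writes the trajectory as a multi-model PDB and the ground truth as a JSON
#' sidecar next to it.
#'
#' @param scenario a generator result (list with `trajectory` or
#'   `empty`/`loaded`, and `ground_truth`).
#' @param prefix output path prefix.
#' @return character vector of files written, invisibly.
#' @export
write_scenario <- function(scenario, prefix) {
  files <- character(0)
  if (!is.null(scenario$trajectory)) {
    f <- paste0(prefix, ".pdb")
    write_multimodel_pdb(scenario$trajectory, f)
    files <- c(files, f)
  }
  for (part in c("empty", "loaded")) {
    if (!is.null(scenario[[part]])) {
      f <- paste0(prefix, "_", part, ".pdb")
      write_multimodel_pdb(scenario[[part]], f)
      files <- c(files, f)
    }
  }
  gt <- paste0(prefix, ".ground_truth.json")
  jsonlite::write_json(scenario$ground_truth, gt, auto_unbox = TRUE, digits = NA)
  invisible(c(files, gt))
}
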