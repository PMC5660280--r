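#' Ligand heavy-atom RMSD time series after a protein fit
#'
#' Per frame, the protein-fit atoms are superposed (Kabsch) onto their
#' positions in the reference frame, the transform is applied to the ligand
#' atoms, and the ligand heavy-atom RMSD versus the reference frame is
#' reported WITHOUT a second fit on the ligand — so rigid-body motion of the
#' whole complex reads as zero while genuine ligand displacement (including
#' dissociation) is preserved.
#'
#' @param trajectory a [trajectory()] object.
#' @param ligand ligand selection (heavy atoms filtered automatically).
#' @param protein_fit selection of >= 3 atoms used for the superposition.
#' @param reference_frame frame index used as reference (default 1).
#' @return numeric per-frame RMSD series, Angstrom.
#' @export
ligand_rmsd_series <- function(trajectory, ligand, protein_fit, reference_frame = 1L) {
  lidx <- .resolve_selection(trajectory, ligand, "ligand")
  fidx <- .resolve_selection(trajectory, protein_fit, "protein_fit")
  heavy <- toupper(trajectory$topology$element[lidx]) != "H"
  lidx <- lidx[heavy]
  if (!length(lidx)) stop("ligand selection has no heavy atoms")
  if (length(fidx) < 3L) stop("protein_fit needs at least 3 atoms")
  nf <- n_frames(trajectory)
  if (reference_frame < 1L || reference_frame > nf) stop("invalid reference frame")
  ref <- trajectory$frames[[reference_frame]]
  ref_fit <- ref[fidx, , drop = FALSE]
  ref_lig <- ref[lidx, , drop = FALSE]
  vapply(trajectory$frames, function(f) {
    fit <- kabsch_superpose(f[fidx, , drop = FALSE], ref_fit)
    rmsd(apply_superposition(f[lidx, , drop = FALSE], fit), ref_lig)
  }, 0.0)
}

# atoms shared by trajectory and reference topology, matched by
# (resno, atom name); returns a data.frame of index pairs
.match_atoms <- function(top_a, idx_a, top_b) {
  key_a <- paste(top_a$resno[idx_a], top_a$name[idx_a])
  key_b <- paste(top_b$resno, top_b$name)
  hit <- match(key_a, key_b)
  data.frame(a = idx_a[!is.na(hit)], b = hit[!is.na(hit)])
}

#' Per-residue heavy-atom RMSD matrix versus a reference structure
#'
#' Each frame is first superposed globally on the `fit` selection (default:
#' C-alpha atoms shared by trajectory and reference); per-residue heavy-atom
#' RMSDs versus the reference are then computed WITHOUT per-residue
#' refitting, so collective displacements of whole segments (e.g. a lid
#' region closing over a binding groove) remain visible. Atoms are matched
#' across systems by (residue number, atom name); residues with no matchable
#' heavy atoms are listed in the `skipped` report, never silently dropped.
#'
#' @param trajectory a [trajectory()] object.
#' @param reference a one-or-more-frame [trajectory()]; its first frame is
#'   the reference structure.
#' @param residues residue numbers to analyse (default: all residues shared
#'   with the reference).
#' @param fit selection used for the global fit; default C-alpha atoms
#'   (name "CA", element C) present in both systems.
#' @return object of class `PerResidueRMSDMatrix`: `matrix`
#'   (frames x residues, Angstrom, columns named by residue number),
#'   `residues`, `skipped`, `reference` description.
#' @export
per_residue_rmsd <- function(trajectory, reference, residues = NULL, fit = NULL) {
  stopifnot(inherits(reference, "Trajectory"))
  top <- trajectory$topology
  rtop <- reference$topology
  ref <- reference$frames[[1L]]
  if (is.null(residues)) {
    # every residue of the analysed trajectory; ones the reference cannot
    # match end up in the skipped-residues report
    residues <- sort(unique(top$resno))
  }
  if (is.null(fit)) {
    ca <- which(top$name == "CA" & toupper(top$element) == "C")
    pairs_fit <- .match_atoms(top, ca, rtop)
  } else {
    fidx <- .resolve_selection(trajectory, fit, "fit")
    pairs_fit <- .match_atoms(top, fidx, rtop)
  }
  if (nrow(pairs_fit) < 3L) stop("fewer than 3 matchable fit atoms")
  ref_fit <- ref[pairs_fit$b, , drop = FALSE]

  res_pairs <- list()
  skipped <- integer(0)
  for (r in residues) {
    idx <- which(top$resno == r & toupper(top$element) != "H")
    p <- .match_atoms(top, idx, rtop)
    # keep only matches landing on the same residue in the reference
    p <- p[rtop$resno[p$b] == r, , drop = FALSE]
    if (nrow(p) == 0L) skipped <- c(skipped, r) else res_pairs[[as.character(r)]] <- p
  }
  kept <- as.integer(names(res_pairs))
  nf <- n_frames(trajectory)
  M <- matrix(NA_real_, nrow = nf, ncol = length(kept),
              dimnames = list(NULL, names(res_pairs)))
  for (i in seq_len(nf)) {
    f <- trajectory$frames[[i]]
    tr <- kabsch_superpose(f[pairs_fit$a, , drop = FALSE], ref_fit)
    fT <- apply_superposition(f, tr)
    for (j in seq_along(res_pairs)) {
      p <- res_pairs[[j]]
      M[i, j] <- rmsd(fT[p$a, , drop = FALSE], ref[p$b, , drop = FALSE])
    }
  }
  structure(
    list(matrix = M, residues = kept, skipped = skipped,
         reference = "frame 1 of supplied reference trajectory"),
    class = "PerResidueRMSDMatrix"
  )
}

#' @export
print.PerResidueRMSDMatrix <- function(x, ...) {
  cat(sprintf("PerResidueRMSDMatrix: %d frame(s) x %d residue(s)",
              nrow(x$matrix), ncol(x$matrix)))
  if (length(x$skipped)) {
    cat(sprintf("; skipped residues: %s", paste(x$skipped, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Fluctuation-corrected per-residue RMSD heatmap
#'
#' Subtracts, from the loaded-versus-reference matrix, the per-residue mean
#' of the apo system's self-comparison matrix (its "natural fluctuation"
#' baseline), then clamps at zero — the corrected map highlights only where
#' the loaded system deviates beyond the apo system's intrinsic mobility.
#'
#' @param loaded [per_residue_rmsd()] of the ligand-bound trajectory versus
#'   the apo reference.
#' @param empty_self [per_residue_rmsd()] of the apo trajectory versus its
#'   own first frame.
#' @return object of class `CorrectedHeatmap`: `matrix` (clamped at 0),
#'   `baseline` (per-residue mean fluctuation, Angstrom).
#' @export
corrected_heatmap <- function(loaded, empty_self) {
  stopifnot(inherits(loaded, "PerResidueRMSDMatrix"),
            inherits(empty_self, "PerResidueRMSDMatrix"))
  if (!identical(colnames(loaded$matrix), colnames(empty_self$matrix))) {
    offenders <- union(
      setdiff(colnames(loaded$matrix), colnames(empty_self$matrix)),
      setdiff(colnames(empty_self$matrix), colnames(loaded$matrix))
    )
    stop("residue columns do not match; offending residues: ",
         paste(offenders, collapse = ", "))
  }
  baseline <- colMeans(empty_self$matrix)
  corrected <- pmax(sweep(loaded$matrix, 2, baseline), 0)
  structure(
    list(matrix = corrected, baseline = baseline, residues = loaded$residues),
    class = "CorrectedHeatmap"
  )
}

#' @export
print.CorrectedHeatmap <- function(x, ...) {
  top <- sort(colMeans(x$matrix), decreasing = TRUE)
  k <- min(5L, length(top))
  cat(sprintf("CorrectedHeatmap: %d frame(s) x %d residue(s); top residues: %s\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s (%.2f A)", names(top)[seq_len(k)], top[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

#' @export
plot.CorrectedHeatmap <- function(x, ...) {
  graphics::image(
    x = seq_len(nrow(x$matrix)), y = seq_len(ncol(x$matrix)),
    z = x$matrix, xlab = "frame", ylab = "residue", axes = FALSE, ...
  )
  graphics::axis(1)
  graphics::axis(2, at = seq_len(ncol(x$matrix)), labels = colnames(x$matrix))
  invisible(x)
}

#' Write a frames-x-residues matrix as delimited text
#'
#' The header row carries residue numbers, so the file can be replotted by
#' any heat-map tool.
#'
#' @param x a `PerResidueRMSDMatrix` or `CorrectedHeatmap`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_heatmap_matrix <- function(x, path) {
  M <- x$matrix
  utils::write.table(
    cbind(frame = seq_len(nrow(M)), as.data.frame(M, check.names = FALSE)),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Mean sidechain heavy-atom RMSD versus a reference frame
#'
#' Sidechain = heavy atoms excluding the backbone names N, CA, C, O. After a
#' global C-alpha fit per frame, per-residue sidechain RMSDs versus the
#' reference frame are averaged over frames and residues. Residues without
#' sidechain heavy atoms (glycine) are skipped and reported.
#'
#' @param trajectory a [trajectory()] object.
#' @param residues residue numbers to include.
#' @param reference_frame frame index used as reference (default 1).
#' @param fit optional fit selection; default all C-alpha atoms.
#' @return list with `mean` (Angstrom, `NA` if no residue had sidechain
#'   atoms), `per_residue` (named mean per residue), `skipped`.
#' @export
mean_sidechain_rmsd <- function(trajectory, residues, reference_frame = 1L, fit = NULL) {
  top <- trajectory$topology
  backbone <- c("N", "CA", "C", "O")
  fidx <- if (is.null(fit)) {
    which(top$name == "CA" & toupper(top$element) == "C")
  } else {
    .resolve_selection(trajectory, fit, "fit")
  }
  if (length(fidx) < 3L) stop("fewer than 3 fit atoms")
  sets <- list()
  skipped <- integer(0)
  for (r in residues) {
    idx <- which(top$resno == r & toupper(top$element) != "H" & !(top$name %in% backbone))
    if (!length(idx)) skipped <- c(skipped, r) else sets[[as.character(r)]] <- idx
  }
  if (!length(sets)) {
    warning("no residues with sidechain heavy atoms; nothing to average")
    return(list(mean = NA_real_, per_residue = numeric(0), skipped = skipped))
  }
  ref <- trajectory$frames[[reference_frame]]
  ref_fit <- ref[fidx, , drop = FALSE]
  nf <- n_frames(trajectory)
  per_res <- matrix(0, nrow = nf, ncol = length(sets),
                    dimnames = list(NULL, names(sets)))
  for (i in seq_len(nf)) {
    f <- trajectory$frames[[i]]
    tr <- kabsch_superpose(f[fidx, , drop = FALSE], ref_fit)
    fT <- apply_superposition(f, tr)
    for (j in seq_along(sets)) {
      idx <- sets[[j]]
      per_res[i, j] <- rmsd(fT[idx, , drop = FALSE], ref[idx, , drop = FALSE])
    }
  }
  list(
    mean = mean(per_res),
    per_residue = colMeans(per_res),
    skipped = skipped
  )
}
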