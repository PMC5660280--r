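#' Geometric hydrogen-bond criteria
#'
#' A donor-H...acceptor triple counts as hydrogen bonded in a frame when the
#' hydrogen-acceptor distance is below `max_ha_distance` and the deviation
#' from linearity is below `max_deviation_angle`. The deviation angle is, by
#' default, measured at the donor between the donor->hydrogen and the
#' donor->acceptor vectors (0 deg = perfectly linear bond); `angle_vertex =
#' "acceptor"` instead measures the acceptor-vertex angle between
#' acceptor->donor and acceptor->hydrogen. Both conventions give 0 for a
#' linear bond; which one a given study used is rarely stated, so both are
#' supported.
#'
#' @param max_ha_distance maximum hydrogen-acceptor distance, Angstrom
#'   (default 3.0).
#' @param max_deviation_angle maximum deviation-from-linearity angle, degrees
#'   (default 35).
#' @param angle_vertex `"donor"` (default) or `"acceptor"`.
#' @return object of class `HBondCriteria`.
#' @export
hbond_criteria <- function(max_ha_distance = 3.0, max_deviation_angle = 35,
                           angle_vertex = c("donor", "acceptor")) {
  stopifnot(max_ha_distance > 0, max_deviation_angle > 0)
  structure(
    list(
      max_ha_distance = max_ha_distance,
      max_deviation_angle = max_deviation_angle,
      angle_vertex = match.arg(angle_vertex)
    ),
    class = "HBondCriteria"
  )
}

#' Donor-hydrogen-acceptor triple
#'
#' `acceptor` may be a single index or a selection of several candidate
#' acceptors; in the latter case the closest acceptor is used per frame.
#'
#' @param donor,hydrogen single topology indices.
#' @param acceptor topology index or index vector (closest member per frame).
#' @return object of class `HBondTriple`.
#' @export
hbond_triple <- function(donor, hydrogen, acceptor) {
  stopifnot(length(donor) == 1L, length(hydrogen) == 1L, length(acceptor) >= 1L)
  structure(
    list(donor = as.integer(donor), hydrogen = as.integer(hydrogen),
         acceptor = as.integer(acceptor)),
    class = "HBondTriple"
  )
}

.closest_acceptor <- function(frame, triple) {
  h <- frame[triple$hydrogen, ]
  acc <- frame[triple$acceptor, , drop = FALSE]
  d <- sqrt(rowSums(sweep(acc, 2, h)^2))
  list(index = triple$acceptor[which.min(d)], distance = min(d))
}

#' Evaluate the hydrogen-bond criteria in one frame
#'
#' @param frame `n x 3` coordinate matrix (one trajectory frame).
#' @param triple an [hbond_triple()].
#' @param criteria an [hbond_criteria()].
#' @return logical.
#' @export
is_hbonded <- function(frame, triple, criteria = hbond_criteria()) {
  stopifnot(inherits(triple, "HBondTriple"), inherits(criteria, "HBondCriteria"))
  idx <- c(triple$donor, triple$hydrogen, triple$acceptor)
  if (any(idx < 1L | idx > nrow(frame))) stop("triple index out of range")
  acc <- .closest_acceptor(frame, triple)
  if (acc$distance >= criteria$max_ha_distance) return(FALSE)
  D <- frame[triple$donor, ]
  H <- frame[triple$hydrogen, ]
  A <- frame[acc$index, ]
  dev <- if (criteria$angle_vertex == "donor") {
    vec_angle(H, D, A)  # between D->H and D->A
  } else {
    vec_angle(D, A, H)  # between A->D and A->H
  }
  dev < criteria$max_deviation_angle
}

#' Hydrogen-bond occupancy and mean distance over a trajectory
#'
#' Occupancy is the percentage of frames satisfying [is_hbonded()]. The mean
#' distance is the hydrogen-acceptor distance (closest acceptor per frame)
#' averaged over ALL frames, bonded or not — occupancy tables pair low
#' occupancies with long mean distances, which is only possible under this
#' convention.
#'
#' @param trajectory a [trajectory()] object.
#' @param triple an [hbond_triple()].
#' @param criteria an [hbond_criteria()].
#' @return object of class `ContactStat`: `mean_distance` (Angstrom),
#'   `occupancy` (percent), `n_frames`.
#' @export
hbond_occupancy <- function(trajectory, triple, criteria = hbond_criteria()) {
  nf <- n_frames(trajectory)
  if (nf < 1L) stop("trajectory has no frames")
  bonded <- logical(nf)
  dist <- numeric(nf)
  for (i in seq_len(nf)) {
    f <- trajectory$frames[[i]]
    dist[i] <- .closest_acceptor(f, triple)$distance
    bonded[i] <- is_hbonded(f, triple, criteria)
  }
  structure(
    list(
      mean_distance = mean(dist),
      occupancy = 100 * sum(bonded) / nf,
      n_frames = nf,
      bonded = bonded,
      distances = dist
    ),
    class = "ContactStat"
  )
}

#' @export
print.ContactStat <- function(x, ...) {
  cat(sprintf("ContactStat: mean distance %.2f A, occupancy %.1f%% over %d frame(s)\n",
              x$mean_distance, x$occupancy, x$n_frames))
  invisible(x)
}

#' Closest-atom distance series between two groups
#'
#' Per frame, the minimum over all cross pairs of atom-atom distances.
#'
#' @param trajectory a [trajectory()] object.
#' @param group_a,group_b non-empty selections.
#' @return list with `series` (per-frame minimum distance, Angstrom) and
#'   `mean`.
#' @export
distance_series <- function(trajectory, group_a, group_b) {
  ia <- .resolve_selection(trajectory, group_a, "group_a")
  ib <- .resolve_selection(trajectory, group_b, "group_b")
  if (!length(ia) || !length(ib)) stop("distance_series: empty selection")
  series <- vapply(trajectory$frames, function(f) {
    A <- f[ia, , drop = FALSE]
    B <- f[ib, , drop = FALSE]
    # pairwise squared distances via outer sums
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    sqrt(max(0, min(d2)))
  }, 0.0)
  list(series = series, mean = mean(series))
}

#' Classify an aromatic ring pair as parallel-displaced or T-shaped
#'
#' Ring planes are least-squares best-fit planes (smallest principal
#' component of the centred ring coordinates); rings whose RMS out-of-plane
#' residual exceeds `planarity_tol` are rejected. The inter-plane angle theta
#' is folded to `[0, 90]` degrees. With centroid distance d:
#' parallel-displaced if `d <= d_max` and `theta <= theta_par`; T-shaped if
#' `d <= d_max` and `theta >= theta_perp`; otherwise unclassified.
#' The default thresholds (6.5 A, 30 deg, 60 deg) are conventional geometric
#' gates for pi-stacking surveys, not derived quantities.
#'
#' @param frame `n x 3` coordinate matrix.
#' @param ring_a,ring_b selections of >= 3 ring atoms each (indices).
#' @param d_max maximum centroid-centroid distance, Angstrom.
#' @param theta_par maximum plane angle for parallel-displaced, degrees.
#' @param theta_perp minimum plane angle for T-shaped, degrees.
#' @param planarity_tol RMS best-fit-plane residual limit, Angstrom.
#' @return character scalar: `"parallel_displaced"`, `"t_shaped"` or
#'   `"unclassified"`, with attributes `distance` and `angle`.
#' @export
classify_stacking <- function(frame, ring_a, ring_b, d_max = 6.5,
                              theta_par = 30, theta_perp = 60,
                              planarity_tol = 0.3) {
  plane <- function(idx, label) {
    if (length(idx) < 3L) stop(label, ": a ring needs at least 3 atoms")
    X <- frame[idx, , drop = FALSE]
    ctr <- colMeans(X)
    Xc <- sweep(X, 2, ctr)
    sv <- svd(Xc)
    normal <- sv$v[, 3]
    resid <- sqrt(mean((Xc %*% normal)^2))
    if (resid > planarity_tol) {
      stop(sprintf("%s: ring is not planar (RMS residual %.3f A > %.3f A)",
                   label, resid, planarity_tol))
    }
    list(centroid = ctr, normal = normal)
  }
  pa <- plane(ring_a, "ring_a")
  pb <- plane(ring_b, "ring_b")
  d <- vec_distance(pa$centroid, pb$centroid)
  cosang <- abs(sum(pa$normal * pb$normal))
  theta <- acos(min(1, cosang)) * 180 / pi  # folded to [0, 90]
  cls <- if (d <= d_max && theta <= theta_par) {
    "parallel_displaced"
  } else if (d <= d_max && theta >= theta_perp) {
    "t_shaped"
  } else {
    "unclassified"
  }
  structure(cls, distance = d, angle = theta)
}

#' Per-frame stacking class fractions over a trajectory
#'
#' @param trajectory a [trajectory()] object.
#' @param ring_a,ring_b ring selections.
#' @param ... passed to [classify_stacking()].
#' @return named fractions over
#'   `c(parallel_displaced, t_shaped, unclassified)`.
#' @export
stacking_fractions <- function(trajectory, ring_a, ring_b, ...) {
  ia <- .resolve_selection(trajectory, ring_a, "ring_a")
  ib <- .resolve_selection(trajectory, ring_b, "ring_b")
  cls <- vapply(trajectory$frames, function(f) {
    as.character(classify_stacking(f, ia, ib, ...))
  }, "")
  levels <- c("parallel_displaced", "t_shaped", "unclassified")
  out <- vapply(levels, function(l) mean(cls == l), 0.0)
  names(out) <- levels
  out
}

#' Write an occupancy/distance table as delimited text
#'
#' One row per contact: residue, functional group, mean distance, occupancy.
#'
#' @param contacts data.frame with columns `residue`, `group`,
#'   `mean_distance`, `occupancy`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_contact_table <- function(contacts, path) {
  stopifnot(all(c("residue", "group", "mean_distance", "occupancy") %in% names(contacts)))
  utils::write.table(contacts, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
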