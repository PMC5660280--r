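# Counting convention for all cutoff-based statistics: a partner is "inside"
# when distance < cutoff, with ties at machine precision (1e-9 A) counted as
# inside. Fixed so integer-valued tests are exact.
.CUTOFF_EPS <- 1e-9

.center_index <- function(trajectory, center) {
  idx <- .resolve_selection(trajectory, center, "center")
  if (length(idx) != 1L) {
    stop(sprintf("center selection must resolve to exactly 1 atom, got %d", length(idx)))
  }
  idx
}

.partner_distances <- function(frame, center_idx, partner_idx) {
  if (!length(partner_idx)) return(numeric(0))
  d <- sweep(frame[partner_idx, , drop = FALSE], 2, frame[center_idx, ])
  sqrt(rowSums(d^2))
}

#' Ion-centred radial distribution profile
#'
#' Bins, per frame, the distances from a single central atom to a partner
#' selection, and averages the per-bin counts over frames. The profile stores
#' mean counts per bin ("arbitrary units"), not a bulk-normalised g(r): for an
#' ion buried in a protein interior a bulk density is ill-defined, and only
#' the running number integral is used quantitatively. The number integral at
#' bin i is the cumulative sum of mean counts up to that bin, i.e. the mean
#' number of partners within the bin's upper edge.
#'
#' @param trajectory a [trajectory()] object.
#' @param center selection resolving to exactly one atom (index vector or
#'   criteria list, see [select_atoms()]).
#' @param partners partner selection; the central atom is excluded if present.
#' @param bin_width bin width in Angstrom (default 0.05).
#' @param r_max histogram range in Angstrom (default 10).
#' @return object of class `RDFProfile`: `bin_edges`, `bin_mid`, `density`
#'   (mean count per bin per frame), `number_integral`, `n_frames`, `r_max`.
#' @export
compute_rdf <- function(trajectory, center, partners, bin_width = 0.05, r_max = 10) {
  stopifnot(bin_width > 0, r_max > bin_width)
  cidx <- .center_index(trajectory, center)
  pidx <- setdiff(.resolve_selection(trajectory, partners, "partners"), cidx)
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, edges[length(edges)] + bin_width)
  nbin <- length(edges) - 1L
  counts <- numeric(nbin)
  nf <- n_frames(trajectory)
  for (f in trajectory$frames) {
    d <- .partner_distances(f, cidx, pidx)
    d <- d[d < edges[nbin + 1L]]
    if (length(d)) {
      bin <- pmin(pmax(findInterval(d, edges), 1L), nbin)
      tab <- tabulate(bin, nbins = nbin)
      counts <- counts + tab
    }
  }
  density <- counts / nf
  structure(
    list(
      bin_edges = edges,
      bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
      density = density,
      number_integral = cumsum(density),
      n_frames = nf,
      r_max = r_max
    ),
    class = "RDFProfile"
  )
}

#' @export
print.RDFProfile <- function(x, ...) {
  pk <- if (any(x$density > 0)) x$bin_mid[which.max(x$density)] else NA_real_
  cat(sprintf(
    "RDFProfile: %d bins to %.2f A, %d frame(s); max-density bin at %.2f A; integral at r_max %.3f\n",
    length(x$density), x$r_max, x$n_frames, pk,
    x$number_integral[length(x$number_integral)]
  ))
  invisible(x)
}

#' @export
plot.RDFProfile <- function(x, ...) {
  graphics::plot(x$bin_mid, x$density, type = "l", xlab = "r (A)",
                 ylab = "mean pair count per bin", ...)
  graphics::lines(x$bin_mid, x$number_integral, col = 2)
  graphics::legend("topleft", legend = c("density", "number integral"),
                   col = c(1, 2), lty = 1, bty = "n")
  invisible(x)
}

#' Running number integral of an RDF at a radius
#' @param profile an [compute_rdf()] profile.
#' @param r radius in Angstrom.
#' @return mean partner count within `r` (value of the integral at the bin
#'   containing `r`).
#' @export
rdf_number_at <- function(profile, r) {
  stopifnot(inherits(profile, "RDFProfile"))
  if (r <= 0) return(0)
  i <- findInterval(r, profile$bin_edges, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(profile$number_integral))
  profile$number_integral[i]
}

#' First minimum of an RDF after the first peak
#'
#' Scans the profile for the first peak, then returns the bin centre of the
#' lowest-density bin strictly between that peak and the next rise. A plateau
#' of equal minima returns the smallest r. By default the scan runs on a
#' 3-bin moving-average smoothed copy of the histogram to avoid shot-noise
#' minima; the returned value is always a raw bin centre.
#'
#' @param profile an [compute_rdf()] profile.
#' @param smooth apply the 3-bin moving average before scanning (default TRUE).
#' @return first-minimum position in Angstrom.
#' @export
detect_first_minimum <- function(profile, smooth = TRUE) {
  stopifnot(inherits(profile, "RDFProfile"))
  dens <- profile$density
  if (all(dens == 0)) stop("profile has no nonzero first peak")
  s <- if (isTRUE(smooth)) stats::filter(dens, rep(1 / 3, 3), sides = 2) else dens
  s <- as.numeric(s)
  # edge bins of the moving average: fall back to raw values
  s[is.na(s)] <- dens[is.na(s)]
  n <- length(s)
  # first peak: first index after the profile becomes nonzero at which the
  # smoothed density stops increasing
  first_nz <- which(s > 0)[1]
  i <- first_nz
  while (i < n && s[i + 1] >= s[i]) i <- i + 1L
  peak <- i
  if (peak >= n) stop("no interior minimum: profile is monotone after the first peak")
  # descend to the minimum plateau, then require a subsequent rise
  j <- peak
  while (j < n && s[j + 1] <= s[j]) j <- j + 1L
  if (j >= n || s[j + 1] <= s[j]) stop("no interior minimum: no rise after the first peak")
  plateau_value <- s[j]
  k <- j
  while (k > peak && s[k - 1] == plateau_value) k <- k - 1L
  profile$bin_mid[k]
}

#' Per-frame coordination-number series around a central atom
#'
#' Counts, per frame, the partner atoms within `cutoff` of the central atom
#' (strictly-less-than convention, machine-precision ties inside) and reports
#' the mean coordination number. The peak position and first minimum of the
#' matching RDF are attached when they can be computed.
#'
#' @inheritParams compute_rdf
#' @param cutoff counting cutoff in Angstrom (e.g. the RDF first minimum).
#' @return object of class `CoordinationResult`: `cutoff`, `per_frame_cn`,
#'   `mean_cn`, `peak_position`, `first_minimum`.
#' @export
coordination_series <- function(trajectory, center, partners, cutoff,
                                bin_width = 0.05, r_max = 10) {
  stopifnot(cutoff > 0)
  cidx <- .center_index(trajectory, center)
  pidx <- setdiff(.resolve_selection(trajectory, partners, "partners"), cidx)
  cn <- vapply(trajectory$frames, function(f) {
    sum(.partner_distances(f, cidx, pidx) < cutoff + .CUTOFF_EPS)
  }, 0L)
  prof <- compute_rdf(trajectory, cidx, pidx, bin_width = bin_width, r_max = r_max)
  peak <- if (any(prof$density > 0)) prof$bin_mid[which.max(prof$density)] else NA_real_
  fmin <- tryCatch(detect_first_minimum(prof), error = function(e) NA_real_)
  structure(
    list(
      cutoff = cutoff,
      per_frame_cn = cn,
      mean_cn = mean(cn),
      peak_position = peak,
      first_minimum = fmin
    ),
    class = "CoordinationResult"
  )
}

#' @export
print.CoordinationResult <- function(x, ...) {
  cat(sprintf(
    "CoordinationResult: mean CN %.2f within %.2f A over %d frame(s); RDF peak %.2f A, first minimum %s A\n",
    x$mean_cn, x$cutoff, length(x$per_frame_cn), x$peak_position,
    ifelse(is.na(x$first_minimum), "NA", sprintf("%.2f", x$first_minimum))
  ))
  invisible(x)
}

#' Denticity fractions of a two-oxygen (carboxylate) group
#'
#' Classifies every frame by how many of the two oxygens lie within `cutoff`
#' of the central ion: 2 = bidentate, 1 = monodentate, 0 = unbound.
#'
#' @inheritParams coordination_series
#' @param oxygen_pair selection resolving to exactly 2 atoms.
#' @return named numeric vector `c(bidentate, monodentate, unbound)` of frame
#'   fractions summing to 1.
#' @export
denticity_fractions <- function(trajectory, center, oxygen_pair, cutoff) {
  cidx <- .center_index(trajectory, center)
  oidx <- .resolve_selection(trajectory, oxygen_pair, "oxygen_pair")
  if (length(oidx) != 2L) {
    stop(sprintf("oxygen_pair must resolve to exactly 2 atoms, got %d", length(oidx)))
  }
  counts <- vapply(trajectory$frames, function(f) {
    sum(.partner_distances(f, cidx, oidx) < cutoff + .CUTOFF_EPS)
  }, 0L)
  nf <- length(counts)
  c(
    bidentate = sum(counts == 2L) / nf,
    monodentate = sum(counts == 1L) / nf,
    unbound = sum(counts == 0L) / nf
  )
}

#' Mean partner count within a radius
#'
#' Equals the RDF number integral evaluated at the same radius; provided as a
#' direct per-frame count for solvent-accessibility statements such as the
#' mean number of water oxygens within 5 A of the ion.
#'
#' @inheritParams coordination_series
#' @param radius counting radius in Angstrom.
#' @return mean over frames of the partner count within `radius`.
#' @export
mean_count_within <- function(trajectory, center, partners, radius) {
  if (radius <= 0) return(0)
  cidx <- .center_index(trajectory, center)
  pidx <- setdiff(.resolve_selection(trajectory, partners, "partners"), cidx)
  mean(vapply(trajectory$frames, function(f) {
    sum(.partner_distances(f, cidx, pidx) < radius + .CUTOFF_EPS)
  }, 0L))
}

#' Export an RDF profile as delimited text plus a JSON sidecar
#'
#' @param profile an [compute_rdf()] profile.
#' @param path output path for the two-column (r, value) tables; `.density.tsv`
#'   and `.integral.tsv` suffixes are appended, and a `.json` sidecar records
#'   `n_frames` and the binning.
#' @param meta optional named list merged into the sidecar (e.g. cutoff,
#'   selections).
#' @return invisibly, the vector of files written.
#' @export
export_rdf <- function(profile, path, meta = list()) {
  stopifnot(inherits(profile, "RDFProfile"))
  f_d <- paste0(path, ".density.tsv")
  f_i <- paste0(path, ".integral.tsv")
  f_j <- paste0(path, ".json")
  utils::write.table(
    data.frame(r = profile$bin_mid, density = profile$density),
    f_d, sep = "\t", row.names = FALSE, quote = FALSE
  )
  utils::write.table(
    data.frame(r = profile$bin_mid, number_integral = profile$number_integral),
    f_i, sep = "\t", row.names = FALSE, quote = FALSE
  )
  sidecar <- c(list(
    n_frames = profile$n_frames,
    bin_width = diff(profile$bin_edges[1:2]),
    r_max = profile$r_max
  ), meta)
  jsonlite::write_json(sidecar, f_j, auto_unbox = TRUE, digits = NA)
  invisible(c(f_d, f_i, f_j))
}
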