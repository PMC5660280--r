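#' Default van der Waals radii (Bondi set), Angstrom
#'
#' Covers the elements occurring in a solvent-stripped protein-ligand-ion
#' complex: H, C, N, O, S, P, F, Cl, Br, Zn, Ca. Values are the Bondi
#' compilation (Zn and Ca from its metal extension).
#'
#' @return named numeric vector, element symbol -> radius (Angstrom).
#' @export
default_vdw_radii <- function() {
  c(
    H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, Cl = 1.75, Br = 1.85, Zn = 1.39, Ca = 2.31
  )
}

#' Shrake-Rupley SASA configuration
#'
#' @param probe_radius solvent probe radius, Angstrom (default 1.4, water).
#' @param n_sphere_points test points per atom (default 960; >= 60).
#' @param radii named element -> radius table, Angstrom.
#' @param orientation optional 3x3 rotation applied to the test-point
#'   lattice. The lattice is deterministic (Fibonacci), so rotating a
#'   structure changes which points graze occluders; passing the same
#'   rotation here keeps results exactly invariant under rigid motion.
#' @return object of class `SasaConfig`.
#' @export
sasa_config <- function(probe_radius = 1.4, n_sphere_points = 960,
                        radii = default_vdw_radii(), orientation = NULL) {
  stopifnot(probe_radius >= 0, n_sphere_points >= 60, all(radii > 0))
  if (!is.null(orientation)) {
    stopifnot(is.matrix(orientation), all(dim(orientation) == c(3L, 3L)))
  }
  structure(
    list(probe_radius = probe_radius, n_sphere_points = as.integer(n_sphere_points),
         radii = radii, orientation = orientation),
    class = "SasaConfig"
  )
}

# Deterministic, seedless unit-sphere point set (Fibonacci lattice).
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

.radii_for <- function(elements, radii) {
  key <- paste0(toupper(substr(elements, 1, 1)), tolower(substr(elements, 2, 3)))
  r <- radii[key]
  if (any(is.na(r))) {
    stop("no van der Waals radius defined for element(s): ",
         paste(unique(key[is.na(r)]), collapse = ", "))
  }
  as.numeric(r)
}

#' Shrake-Rupley solvent-accessible surface area of one frame
#'
#' Each target atom's probe-inflated sphere is sampled with a deterministic
#' Fibonacci point lattice; a test point is accessible unless it lies inside
#' another atom's inflated sphere. A point exactly on another sphere's
#' surface (within 1e-9 A) is occluded only by atoms that precede the owner
#' in topology order, so coincident duplicate atoms partition the surface
#' rather than double-count it. Per-atom area = accessible fraction x
#' 4 pi (r_atom + probe)^2. Occlusion is tested against all atoms of
#' `target` and `context`.
#'
#' @param frame `n x 3` coordinate matrix, Angstrom.
#' @param elements length-`n` element symbols for `frame` rows.
#' @param target indices of atoms whose area is reported.
#' @param context indices of additional occluding atoms (may be empty).
#' @param config a [sasa_config()].
#' @return numeric per-target-atom areas, Angstrom^2 (named by index).
#' @export
shrake_rupley <- function(frame, elements, target, context = integer(0),
                          config = sasa_config()) {
  stopifnot(inherits(config, "SasaConfig"))
  all_idx <- unique(c(target, context))
  rad <- numeric(nrow(frame))
  rad[all_idx] <- .radii_for(elements[all_idx], config$radii)
  probe <- config$probe_radius
  pts <- .fibonacci_sphere(config$n_sphere_points)
  if (!is.null(config$orientation)) pts <- pts %*% t(config$orientation)
  eps <- 1e-9
  areas <- numeric(length(target))
  for (k in seq_along(target)) {
    i <- target[k]
    ri <- rad[i] + probe
    P <- sweep(pts * ri, 2, frame[i, ], "+")
    occluders <- setdiff(all_idx, i)
    if (length(occluders)) {
      oc <- frame[occluders, , drop = FALSE]
      rj <- rad[occluders] + probe
      # only atoms close enough to touch the sphere can occlude
      dci <- sqrt(rowSums(sweep(oc, 2, frame[i, ])^2))
      near <- which(dci < ri + rj + eps)
      accessible <- rep(TRUE, nrow(P))
      for (m in near) {
        j <- occluders[m]
        d <- sqrt(rowSums(sweep(P, 2, oc[m, ])^2))
        blocked <- d < rj[m] - eps
        tie <- abs(d - rj[m]) <= eps
        if (j < i) blocked <- blocked | tie
        accessible <- accessible & !blocked
        if (!any(accessible)) break
      }
      frac <- mean(accessible)
    } else {
      frac <- 1
    }
    areas[k] <- frac * 4 * pi * ri^2
  }
  names(areas) <- target
  areas
}

#' Per-frame SASA series of a selection with summary statistics
#'
#' @param trajectory a [trajectory()] object.
#' @param target selection whose total SASA is reported per frame.
#' @param context additional occluding selection (e.g. the whole protein and
#'   ions for a ligand-SASA calculation; waters are normally absent from the
#'   solvent-stripped trajectories this is designed for).
#' @param config a [sasa_config()].
#' @param level confidence level in percent for the summary (default 95).
#' @return list with `series` (Angstrom^2 per frame) and `summary`
#'   (a [summarize_series()] result; `sd`/`ci` are `NA` for one frame).
#' @export
sasa_series <- function(trajectory, target, context = integer(0),
                        config = sasa_config(), level = 95) {
  tidx <- .resolve_selection(trajectory, target, "target")
  cidx <- setdiff(.resolve_selection(trajectory, context, "context"), tidx)
  if (!length(tidx)) stop("empty target selection")
  el <- trajectory$topology$element
  series <- vapply(trajectory$frames, function(f) {
    sum(shrake_rupley(f, el, tidx, cidx, config))
  }, 0.0)
  summary <- if (length(series) >= 2L) {
    summarize_series(series, level = level)
  } else {
    structure(list(mean = mean(series), sd = NA_real_, ci_half_width = NA_real_,
                   n = length(series), level = level),
              class = "SummaryStat")
  }
  list(series = series, summary = summary)
}

#' Mean, SD and normal-approximation confidence half-width of a series
#'
#' Uses the sample SD (n-1 denominator) and the normal z-quantile, i.e.
#' half-width = z(level) * sd / sqrt(n) (1.96 at 95%). This is the
#' convention under which a series with SD 12.0 at n = 1000 gives a 95%
#' half-width of 0.7 (and SD 22.7 gives 1.4).
#'
#' @param series numeric vector, n >= 2.
#' @param level confidence level in percent (default 95).
#' @return object of class `SummaryStat`: `mean`, `sd`, `ci_half_width`, `n`,
#'   `level`.
#' @export
summarize_series <- function(series, level = 95) {
  n <- length(series)
  if (n < 2L) stop("need at least 2 values for a summary")
  stopifnot(level > 0, level < 100)
  s <- stats::sd(series)
  z <- stats::qnorm(1 - (1 - level / 100) / 2)
  structure(
    list(mean = mean(series), sd = s, ci_half_width = z * s / sqrt(n),
         n = n, level = level),
    class = "SummaryStat"
  )
}

#' @export
print.SummaryStat <- function(x, ...) {
  cat(sprintf("mean %.1f (+-%.1f, P = %d%%, SD = %.1f, n = %d)\n",
              x$mean, x$ci_half_width, as.integer(x$level), x$sd, x$n))
  invisible(x)
}
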