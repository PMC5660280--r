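# Link-bond parameter table for an RI-BP86-D3 QM region terminated across
# C-alpha/C-beta bonds, one row per (residue type, basis set): rho is the
# fractional position of the link atom along the C-alpha -> C-beta vector,
# r0 (A) and kL (kcal/mol/A^2) define the harmonic correction of the link
# bond. Residue types: Hid/Hie (delta-/epsilon-protonated histidine), Glu,
# Asp, and the two ligand link bonds ROB1/ROB2.
.link_param_table <- local({
  tab <- rbind(
    # type,  basis, rho,    r0,    kL
    c("Hid",  "TZ", 0.7140, 1.560, 139.056),
    c("Hie",  "TZ", 0.7155, 1.561, 145.779),
    c("Glu",  "TZ", 0.7241, 1.547, 170.580),
    c("Asp",  "TZ", 0.7251, 1.543, 145.051),
    c("ROB1", "TZ", 0.7363, 1.507, 235.182),
    c("ROB2", "TZ", 0.7332, 1.515, 240.882),
    c("Hid",  "DZ", 0.7226, 1.564, 143.739),
    c("Hie",  "DZ", 0.7257, 1.561, 176.663),
    c("Glu",  "DZ", 0.7289, 1.554, 187.240),
    c("Asp",  "DZ", 0.7223, 1.548, 127.987),
    c("ROB1", "DZ", 0.7435, 1.514, 242.270),
    c("ROB2", "DZ", 0.7395, 1.519, 245.840)
  )
  data.frame(
    residue_type = tab[, 1], basis = tab[, 2],
    rho = as.numeric(tab[, 3]), r0 = as.numeric(tab[, 4]),
    kL = as.numeric(tab[, 5]), stringsAsFactors = FALSE
  )
})

#' Link-bond parameter table
#'
#' All 12 (residue type, basis) rows of the published link-atom parameter
#' set: rho (dimensionless C-alpha/C-beta distance ratio), r0 (Angstrom) and
#' kL (kcal/mol/Angstrom^2) of the harmonic link-bond correction, for the
#' triple-zeta (TZ) and double-zeta (DZ) basis sets.
#'
#' @return data.frame with columns `residue_type`, `basis`, `rho`, `r0`, `kL`.
#' @export
link_param_table <- function() .link_param_table

#' Look up link-bond parameters for one residue type and basis
#'
#' @param residue_type one of `"Hid"`, `"Hie"`, `"Glu"`, `"Asp"`, `"ROB1"`,
#'   `"ROB2"`.
#' @param basis `"TZ"` or `"DZ"`.
#' @return object of class `LinkBondParams`: `residue_type`, `basis`, `rho`,
#'   `r0`, `kL`.
#' @export
lookup_link_params <- function(residue_type, basis) {
  hit <- .link_param_table$residue_type == residue_type &
    .link_param_table$basis == basis
  if (!any(hit)) {
    stop(sprintf(
      "no link-bond parameters for (%s, %s); valid residue types: %s; valid bases: %s",
      residue_type, basis,
      paste(unique(.link_param_table$residue_type), collapse = ", "),
      paste(unique(.link_param_table$basis), collapse = ", ")
    ))
  }
  row <- .link_param_table[hit, ]
  structure(
    list(residue_type = row$residue_type, basis = row$basis,
         rho = row$rho, r0 = row$r0, kL = row$kL),
    class = "LinkBondParams"
  )
}

#' @export
print.LinkBondParams <- function(x, ...) {
  cat(sprintf("LinkBondParams %s/%s: rho %.4f, r0 %.3f A, kL %.3f kcal/mol/A^2\n",
              x$residue_type, x$basis, x$rho, x$r0, x$kL))
  invisible(x)
}

#' Place a link atom on a cut C-alpha/C-beta bond
#'
#' The link atom sits on the segment at `c_alpha + rho * (c_beta - c_alpha)`.
#'
#' @param c_alpha,c_beta 3-vectors, Angstrom.
#' @param rho distance ratio in (0, 1], from [lookup_link_params()].
#' @return link-atom position, 3-vector Angstrom.
#' @export
place_link_atom <- function(c_alpha, c_beta, rho) {
  stopifnot(length(c_alpha) == 3L, length(c_beta) == 3L, rho > 0)
  if (all(c_alpha == c_beta)) stop("c_alpha and c_beta coincide")
  c_alpha + rho * (c_beta - c_alpha)
}

#' Harmonic link-bond correction energy and force
#'
#' `E(r) = kL (r - r0)^2` by default (force-field convention matching
#' kcal/mol/Angstrom^2 force constants); set `half_factor = TRUE` for the
#' `1/2 kL (r - r0)^2` convention. The returned `force` is the signed
#' restoring force `-dE/dr` along increasing r; its sign always points
#' toward r0. `force_magnitude` is its absolute value.
#'
#' @param r link-bond length, Angstrom (> 0).
#' @param params a [lookup_link_params()] result.
#' @param half_factor use the 1/2 k convention (default FALSE).
#' @return list with `energy` (kcal/mol), `force` (kcal/mol/Angstrom,
#'   signed), `force_magnitude`.
#' @export
link_correction <- function(r, params, half_factor = FALSE) {
  stopifnot(inherits(params, "LinkBondParams"))
  if (r <= 0) stop("link-bond length must be positive")
  k <- if (isTRUE(half_factor)) params$kL / 2 else params$kL
  dr <- r - params$r0
  list(
    energy = k * dr^2,
    force = -2 * k * dr,
    force_magnitude = abs(2 * k * dr)
  )
}

#' Electrostatic-embedding configuration
#'
#' @param scale_factor uniform factor applied to every MM charge used for
#'   embedding (default 0.666, which maps the TIP3P oxygen charge -0.83 e to
#'   the -0.55 e a QM description assigns a bulk water oxygen).
#' @param qm_selection atoms excluded from the point-charge set (they are
#'   treated quantum mechanically); index vector or criteria list.
#' @param precision decimal places for file export (default 6).
#' @return object of class `EmbeddingConfig`.
#' @export
embedding_config <- function(scale_factor = 0.666, qm_selection = integer(0),
                             precision = 6L) {
  stopifnot(scale_factor > 0, scale_factor <= 1)
  structure(
    list(scale_factor = scale_factor, qm_selection = qm_selection,
         precision = as.integer(precision)),
    class = "EmbeddingConfig"
  )
}

#' Scale an MM charge for electrostatic embedding
#'
#' @param raw_charge charge in e (finite).
#' @param config an [embedding_config()] (or a bare numeric factor).
#' @return scaled charge in e.
#' @export
scale_charge <- function(raw_charge, config = embedding_config()) {
  factor <- if (inherits(config, "EmbeddingConfig")) config$scale_factor else config
  stopifnot(all(is.finite(raw_charge)))
  raw_charge * factor
}

#' Export scaled MM point charges for electrostatic embedding
#'
#' Writes the MM atoms (QM-selection atoms excluded) as whitespace-delimited
#' `x y z q` rows, coordinates in Angstrom and charges in e, pre-scaled by
#' the embedding factor.
#'
#' @param frame `n x 3` coordinate matrix, Angstrom.
#' @param mm_atoms indices of the MM atoms.
#' @param raw_charges one raw charge (e) per `mm_atoms` entry.
#' @param config an [embedding_config()].
#' @param path optional output file; omit to only build the set.
#' @return object of class `PointChargeSet`: data.frame `x, y, z, q` (scaled).
#' @export
export_embedding_charges <- function(frame, mm_atoms, raw_charges,
                                     config = embedding_config(), path = NULL) {
  stopifnot(inherits(config, "EmbeddingConfig"))
  if (length(raw_charges) != length(mm_atoms)) {
    stop(sprintf("got %d charges for %d MM atoms", length(raw_charges), length(mm_atoms)))
  }
  qm_idx <- if (length(config$qm_selection)) {
    if (is.numeric(config$qm_selection)) as.integer(config$qm_selection) else
      stop("qm_selection in embedding_config must be resolved indices")
  } else integer(0)
  keep <- !(mm_atoms %in% qm_idx)
  idx <- mm_atoms[keep]
  q <- scale_charge(raw_charges[keep], config)
  out <- data.frame(
    x = frame[idx, 1], y = frame[idx, 2], z = frame[idx, 3], q = q
  )
  class(out) <- c("PointChargeSet", "data.frame")
  if (!is.null(path)) {
    fmt <- sprintf("%%.%df %%.%df %%.%df %%.%df",
                   config$precision, config$precision,
                   config$precision, config$precision)
    writeLines(sprintf(fmt, out$x, out$y, out$z, out$q), path)
  }
  out
}
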