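#' Euclidean distance between two points
#' @param p,q numeric 3-vectors, Angstrom.
#' @return distance in Angstrom.
#' @export
vec_distance <- function(p, q) {
  stopifnot(length(p) == 3L, length(q) == 3L, all(is.finite(p)), all(is.finite(q)))
  sqrt(sum((p - q)^2))
}

#' Angle at a vertex, in degrees
#'
#' Returns the angle a-b-c at vertex `b`, in `[0, 180]` degrees.
#'
#' @param a,b,c numeric 3-vectors.
#' @return angle in degrees.
#' @export
vec_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-length arm in angle computation")
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation (reflections excluded) and translation that
#' minimise the RMSD of `mobile` onto `reference`. Degenerate cases
#' (collinear or < 3 points) still give the minimal RMSD; the rotation is
#' then one deterministic representative fixed by the SVD convention with the
#' smallest-singular-vector sign correction.
#'
#' Points are rows. The fitted coordinates are
#' `mobile %*% t(rotation) + translation` (row-vector convention).
#'
#' @param mobile,reference numeric `n x 3` matrices with equal `n >= 1`.
#' @return object of class `SuperpositionResult`: list with `rotation`
#'   (3x3, det +1), `translation` (3-vector), `rmsd_after` (Angstrom).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3L || ncol(reference) != 3L) {
    stop("mobile and reference must be n x 3 matrices of equal size")
  }
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  H <- crossprod(P, Q)  # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- P %*% t(R)
  rmsd_after <- sqrt(mean(rowSums((fitted - Q)^2)))
  structure(
    list(
      rotation = R,
      translation = as.numeric(cr - R %*% cm),
      rmsd_after = rmsd_after
    ),
    class = "SuperpositionResult"
  )
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("SuperpositionResult: RMSD after fit %.4f A (det R = %+.6f)\n",
              x$rmsd_after, det(x$rotation)))
  invisible(x)
}

#' Apply a SuperpositionResult transform to coordinates
#' @param coords `n x 3` matrix.
#' @param fit a [kabsch_superpose()] result.
#' @return transformed `n x 3` matrix.
#' @export
apply_superposition <- function(coords, fit) {
  stopifnot(inherits(fit, "SuperpositionResult"))
  sweep(as.matrix(coords) %*% t(fit$rotation), 2, fit$translation, "+")
}

#' Root-mean-square deviation between two coordinate sets
#'
#' @param A,B numeric `n x 3` matrices with equal `n`.
#' @param superpose if `TRUE`, compute after an optimal [kabsch_superpose()]
#'   fit of `A` onto `B`.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(A, B, superpose = FALSE) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  if (nrow(A) != nrow(B)) stop("coordinate sets differ in size")
  if (isTRUE(superpose)) {
    return(kabsch_superpose(A, B)$rmsd_after)
  }
  sqrt(mean(rowSums((A - B)^2)))
}
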