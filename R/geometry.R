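# Low-level geometry shared by every analysis: minimum-image displacements,
# pairwise distances under orthorhombic PBC, and angles against the membrane
# normal (+z).  Coordinates are Angstrom throughout, angles degrees.

#' Minimum-image displacement components
#'
#' Wraps per-axis displacements into (-box/2, box/2] for an orthorhombic box.
#'
#' @param d numeric vector or matrix of raw displacements (Angstrom).
#' @param box box edge length(s) along the corresponding axis (Angstrom).
#' @return displacements of the same shape, minimum-image convention.
#' @keywords internal
minImage <- function(d, box) {
  d - box * round(d / box)
}

.checkOrthorhombic <- function(box) {
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive edge lengths (orthorhombic boxes only); ",
         "triclinic boxes are not supported", call. = FALSE)
  invisible(box)
}

#' Pairwise distance matrix under orthorhombic PBC
#'
#' @param a,b coordinate matrices (n x 3 and m x 3, Angstrom).
#' @param box box edges (length-3) or NULL for no periodic wrapping.
#' @return n x m matrix of distances.
#' @keywords internal
pairDistances <- function(a, b, box = NULL) {
  a <- rbind(a); b <- rbind(b)
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dz <- outer(a[, 3], b[, 3], "-")
  if (!is.null(box)) {
    .checkOrthorhombic(box)
    dx <- minImage(dx, box[1]); dy <- minImage(dy, box[2])
    dz <- minImage(dz, box[3])
  }
  sqrt(dx * dx + dy * dy + dz * dz)
}

#' Minimum distance from each row of `a` to the point set `b`
#' @keywords internal
minDistToSet <- function(a, b, box = NULL) {
  d <- pairDistances(a, b, box)
  apply(d, 1L, min)
}

#' Angle between a vector and the +z axis, in degrees within [0, 180]
#' @param v length-3 vector or n x 3 matrix.
#' @keywords internal
angleWithZ <- function(v) {
  v <- rbind(v)
  nrm <- sqrt(rowSums(v * v))
  ang <- rep(NA_real_, nrow(v))
  ok <- nrm > 0
  ct <- pmin(1, pmax(-1, v[ok, 3] / nrm[ok]))
  ang[ok] <- acos(ct) * 180 / pi
  if (nrow(v) == 1L) ang[[1L]] else ang
}

#' Trailing moving average with partial windows at the start
#'
#' The first `w - 1` samples average over what is available, so a constant
#' series maps to itself and the output has the input's length.
#' @keywords internal
movingAverage <- function(x, w) {
  stopifnot(w >= 1L)
  n <- length(x)
  cs <- cumsum(x)
  lo <- pmax(seq_len(n) - w, 0L)
  (cs - c(0, cs)[lo + 1L]) / (seq_len(n) - lo)
}
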