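# Conformational gating metrics: least-squares superposition (Kabsch, via
# SVD), per-residue RMSD after a single global alignment, per-frame RMSD
# series, TM4-TM6 centre-of-mass distances, and pinch-fraction statistics.

#' Optimal least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' matched coordinate sets, mobile onto reference.
#'
#' @param mobile,reference matched n x 3 coordinate matrices (n >= 3,
#'   non-collinear).
#' @return list with `rotation` (3 x 3), `translation` (applied after
#'   rotation), `rmsd`, and `transform(xyz)` applying the fit to arbitrary
#'   coordinates.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    stop("mobile and reference must have matched dimensions")
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 atoms to superpose")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  s <- svd(crossprod(A, B))            # 3x3: A^T B
  if (s$d[2] < 1e-10 * max(s$d[1], 1))
    stop("degenerate (collinear) atom subset: superposition undefined")
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)            # rotation: x_ref ~ R (x - cm) + cr
  fitted <- sweep(tcrossprod(A, R), 2, cr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  transform <- function(xyz)
    sweep(tcrossprod(sweep(as.matrix(xyz), 2, cm), R), 2, cr, "+")
  list(rotation = R, translation = cr - as.vector(R %*% cm), rmsd = rmsd,
       transform = transform)
}

#' Per-residue RMSD between two aligned structures
#'
#' Structures are superposed once on a common reference subset (default:
#' all shared atoms); the RMSD of each residue's atoms is then computed
#' without re-fitting, so large per-residue values report genuine
#' displacement relative to the common frame.
#'
#' @param atomsA,atomsB atom tables of the two structures; residues are
#'   matched on (subunit_id, residue_id, atom_name).
#' @param xyzA,xyzB n x 3 coordinate matrices.
#' @param fit_subset optional logical/integer index into the matched pairs
#'   used for the superposition.
#' @return data.frame `subunit_id`, `residue_id`, `residue_name`, `rmsd`
#'   (Angstrom), plus the global fit as attribute `superposition`.
#' @export
perResidueRMSD <- function(atomsA, xyzA, atomsB, xyzB, fit_subset = NULL) {
  keyA <- paste(atomsA$subunit_id, atomsA$residue_id, atomsA$atom_name,
                sep = "\r")
  keyB <- paste(atomsB$subunit_id, atomsB$residue_id, atomsB$atom_name,
                sep = "\r")
  mA <- match(keyB, keyA)
  if (anyNA(mA)) {
    miss <- unique(paste(atomsB$subunit_id[is.na(mA)],
                         atomsB$residue_id[is.na(mA)]))
    stop("unmatched residue/atom(s) between structures: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  A <- as.matrix(xyzA)[mA, , drop = FALSE]
  B <- as.matrix(xyzB)
  if (is.null(fit_subset)) fit_subset <- seq_len(nrow(B))
  fit <- superpose(A[fit_subset, , drop = FALSE],
                   B[fit_subset, , drop = FALSE])
  Afit <- fit$transform(A)
  d2 <- rowSums((Afit - B)^2)
  grp <- paste(atomsB$subunit_id, atomsB$residue_id, sep = "\r")
  agg <- tapply(d2, grp, function(v) sqrt(mean(v)))
  parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  first <- !duplicated(grp)
  rname <- atomsB$residue_name[first]
  names(rname) <- grp[first]
  out <- data.frame(subunit_id = parts[, 1],
                    residue_id = as.integer(parts[, 2]),
                    residue_name = unname(rname[names(agg)]),
                    rmsd = as.numeric(agg), stringsAsFactors = FALSE,
                    row.names = NULL)
  out <- out[order(out$subunit_id, out$residue_id), , drop = FALSE]
  attr(out, "superposition") <- fit[c("rotation", "translation", "rmsd")]
  out
}

#' Best-fit RMSD of a selection against a reference, per frame
#'
#' @param frames [FrameSet-class].
#' @param reference n x 3 reference coordinates for the selection.
#' @param selection atom indices matched row-by-row to `reference`.
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsdSeries <- function(frames, reference, selection) {
  reference <- as.matrix(reference)
  stopifnot(length(selection) == nrow(reference))
  vapply(seq_len(nFrames(frames)), function(k) {
    xyz <- frameCoords(frames, k)[selection, , drop = FALSE]
    superpose(xyz, reference)$rmsd
  }, 0)
}

#' Centre-of-mass distance between two helix selections, per frame
#'
#' Mass-weighted centres; atoms with unknown elements fall back to unit
#' masses with a warning (see [atomMasses()]).
#'
#' @param atoms atom table.
#' @param frames [FrameSet-class].
#' @param sel_a,sel_b atom indices of the two helices (e.g. TM4 and TM6).
#' @return numeric vector of per-frame distances (Angstrom).
#' @export
tmComDistance <- function(atoms, frames, sel_a, sel_b) {
  if (!length(sel_a) || !length(sel_b))
    stop("both selections must be nonempty")
  ma <- atomMasses(atoms$element[sel_a])
  mb <- atomMasses(atoms$element[sel_b])
  vapply(seq_len(nFrames(frames)), function(k) {
    xyz <- frameCoords(frames, k)
    ca <- colSums(xyz[sel_a, , drop = FALSE] * ma) / sum(ma)
    cb <- colSums(xyz[sel_b, , drop = FALSE] * mb) / sum(mb)
    sqrt(sum((ca - cb)^2))
  }, 0)
}

#' Pinch indicator and pinch fraction of the TM4-TM6 gate
#'
#' A frame is pinched iff, for at least one configured residue pair, the
#' minimum distance between the two residues' sidechain heavy atoms is
#' strictly below the cutoff.  Sidechain heavy atoms are all non-hydrogen
#' atoms outside the backbone set (N, CA, C, O); glycine (no sidechain) in
#' a pair is an error.
#'
#' @param atoms atom table.
#' @param frames [FrameSet-class].
#' @param pair_set data.frame with columns `subunit_id`, `res_a`, `res_b`
#'   (residue ids of the TM4/TM6 partners).
#' @param cutoff pinch cutoff, Angstrom (field convention 3.0, strict <).
#' @param window frame indices for the fraction (default: all).
#' @return list with `pinched` (per-frame logical) and `fraction` (over
#'   the window).
#' @export
pinchFraction <- function(atoms, frames, pair_set, cutoff = 3.0,
                          window = NULL) {
  if (is.null(window)) window <- seq_len(nFrames(frames))
  backbone <- c("N", "CA", "C", "O", "OT1", "OT2")
  sideIdx <- function(sub, res) {
    i <- which(atoms$subunit_id == sub & atoms$residue_id == res &
                 atoms$role == "protein" &
                 !(atoms$atom_name %in% backbone) &
                 atoms$element != "H")
    if (!length(i)) {
      rn <- unique(atoms$residue_name[atoms$subunit_id == sub &
                                        atoms$residue_id == res])
      stop("residue ", res, " (", paste(rn, collapse = "/"), ") in subunit ",
           sub, " has no sidechain heavy atoms (glycine?)")
    }
    i
  }
  pairs <- lapply(seq_len(nrow(pair_set)), function(j)
    list(a = sideIdx(pair_set$subunit_id[j], pair_set$res_a[j]),
         b = sideIdx(pair_set$subunit_id[j], pair_set$res_b[j])))
  nf <- nFrames(frames)
  pinched <- logical(nf)
  for (k in seq_len(nf)) {
    xyz <- frameCoords(frames, k)
    for (pr in pairs) {
      d <- pairDistances(xyz[pr$a, , drop = FALSE],
                         xyz[pr$b, , drop = FALSE], box = frames@box[k, ])
      if (min(d) < cutoff) { pinched[k] <- TRUE; break }
    }
  }
  list(pinched = pinched, fraction = mean(pinched[window]))
}

#' Default TM4-TM6 pinch pair set
#'
#' The inter-helical contact residues at the aqueduct bottleneck: F330,
#' T333, L336, V337 (TM4) against Y439, T443 (TM6), for the given
#' subunits.
#'
#' @param subunits subunit labels.
#' @return data.frame `subunit_id`, `res_a`, `res_b`.
#' @export
defaultPinchPairs <- function(subunits = c("I", "II")) {
  tm4 <- c(330L, 333L, 336L, 337L)
  tm6 <- c(439L, 443L)
  g <- expand.grid(res_a = tm4, res_b = tm6, subunit_id = subunits,
                   stringsAsFactors = FALSE)
  g[, c("subunit_id", "res_a", "res_b")]
}
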