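# Lipid orientation angles: acyl-tail tilt (bisector of the two tails vs
# the membrane normal) and the P-to-N head-group dipole angle.

# atom indices of one lipid residue
.lipidAtomIdx <- function(atoms, lipid_id, subunit = "MEMB") {
  which(atoms$residue_id == lipid_id & atoms$subunit_id == subunit &
          atoms$role %in% c("lipid_head", "lipid_tail"))
}

# split tail carbon indices of one lipid into its two acyl chains by the
# CHARMM C2x/C3x name prefix
.tailChains <- function(atoms, idx) {
  tails <- idx[atoms$role[idx] == "lipid_tail"]
  pre <- substr(atoms$atom_name[tails], 1, 2)
  split(tails, pre)
}

#' Tail tilt angle of a lipid over a trajectory
#'
#' Each acyl tail defines a vector from its first to its last carbon; the
#' tilt is the angle between the normalised bisector of the two tail
#' vectors and +z, in degrees within [0, 180].  An (anti)parallel
#' degenerate bisector gives `NA`.
#'
#' @param atoms atom table.
#' @param frames [FrameSet-class].
#' @param lipid_id,subunit lipid residue id and subunit label.
#' @return numeric vector of per-frame angles (degrees).
#' @export
tailTiltAngles <- function(atoms, frames, lipid_id, subunit = "MEMB") {
  idx <- .lipidAtomIdx(atoms, lipid_id, subunit)
  if (!length(idx)) stop("no such lipid: ", lipid_id)
  chains <- .tailChains(atoms, idx)
  if (length(chains) != 2L ||
      any(vapply(chains, length, 1L) < 2L))
    stop("lipid ", lipid_id, " must have two tails with >= 2 carbons each")
  nf <- nFrames(frames)
  ang <- numeric(nf)
  for (k in seq_len(nf)) {
    xyz <- frameCoords(frames, k)
    vs <- lapply(chains, function(ch) {
      v <- xyz[ch[length(ch)], ] - xyz[ch[1], ]
      n <- sqrt(sum(v * v))
      if (n == 0) return(c(NA, NA, NA))
      v / n
    })
    bis <- vs[[1]] + vs[[2]]
    ang[k] <- if (anyNA(bis) || sqrt(sum(bis * bis)) < 1e-8)
      NA_real_ else angleWithZ(bis)
  }
  ang
}

#' Head-group P-to-N dipole angle of a lipid over a trajectory
#'
#' Angle between the vector from the phosphorus to the head-group nitrogen
#' and +z, in degrees within [0, 180]; obtuse angles mean the phosphate
#' leads the choline/amine group downward.  Also reports the phosphorus z.
#'
#' @param atoms atom table.
#' @param frames [FrameSet-class].
#' @param lipid_id,subunit lipid residue id and subunit label.
#' @return data.frame with `time`, `z_P`, `angle` (degrees; `NA` if P and
#'   N coincide).
#' @export
pnDipoleAngles <- function(atoms, frames, lipid_id, subunit = "MEMB") {
  idx <- .lipidAtomIdx(atoms, lipid_id, subunit)
  if (!length(idx)) stop("no such lipid: ", lipid_id)
  iP <- idx[atoms$element[idx] == "P"]
  iN <- idx[atoms$element[idx] == "N" & atoms$role[idx] == "lipid_head"]
  if (length(iP) != 1L || length(iN) < 1L)
    stop("lipid ", lipid_id, " lacks a P or head-group N atom")
  iN <- iN[1]
  nf <- nFrames(frames)
  out <- data.frame(time = frameTimes(frames), z_P = numeric(nf),
                    angle = numeric(nf))
  for (k in seq_len(nf)) {
    xyz <- frameCoords(frames, k)
    v <- xyz[iN, ] - xyz[iP, ]
    out$z_P[k] <- xyz[iP, 3]
    out$angle[k] <- if (sqrt(sum(v * v)) < 1e-8) NA_real_ else angleWithZ(v)
  }
  out
}
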