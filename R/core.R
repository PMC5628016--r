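# Core membrane-frame conventions: system ingestion, midplane centering,
# leaflet assignment and periodic-boundary unwrapping along z.

#' Load a structure/trajectory pair into an atom table and FrameSet
#'
#' Reads a PDB topology plus a DCD trajectory (or a multi-model PDB serving
#' as both).  Atom roles are assigned from residue/atom-name rules; see
#' [classifyAtoms()].  Atom counts of topology and trajectory must agree.
#'
#' @param topology_path PDB file defining atoms.
#' @param trajectory_path DCD or multi-model PDB with coordinates; `NULL`
#'   uses the topology's own models.
#' @param rules classification rules, see [defaultClassificationRules()].
#' @return list with `atoms` (atom table) and `frames` ([FrameSet-class]).
#' @export
loadSystem <- function(topology_path, trajectory_path = NULL,
                       rules = defaultClassificationRules()) {
  top <- readPDB(topology_path)
  n <- dim(top$coords)[1]
  if (is.null(trajectory_path)) {
    frames <- FrameSet(top$coords,
                       box = if (anyNA(top$box)) c(1, 1, 1) * 1e6 else
                         top$box)
  } else if (grepl("\\.dcd$", trajectory_path, ignore.case = TRUE)) {
    frames <- readDCD(trajectory_path, n_atoms = n)
  } else if (grepl("\\.xtc$", trajectory_path, ignore.case = TRUE)) {
    stop("XTC trajectories are not supported (xdrfile compression is not ",
         "implemented); convert to DCD or multi-model PDB")
  } else {
    trj <- readPDB(trajectory_path)
    if (dim(trj$coords)[1] != n)
      stop("atom count mismatch: topology has ", n, ", trajectory has ",
           dim(trj$coords)[1])
    frames <- FrameSet(trj$coords,
                       box = if (anyNA(trj$box)) c(1, 1, 1) * 1e6 else
                         trj$box)
  }
  role <- classifyAtoms(top$atom_name, top$residue_name, top$residue_id,
                        top$subunit_id, rules)
  atoms <- atomTable(top$atom_name, top$residue_name, top$residue_id,
                     top$subunit_id, role)
  list(atoms = atoms, frames = frames)
}

# indices of lipid head-group phosphorus atoms (the head-group anchors)
.phosphorusIdx <- function(atoms) {
  which(atoms$role == "lipid_head" & atoms$element == "P")
}

#' Center the membrane midplane at z = 0
#'
#' Per frame, all z coordinates are shifted so that the midpoint between the
#' mean z of outer-leaflet phosphorus atoms and the mean z of inner-leaflet
#' phosphorus atoms is zero.  Leaflet membership for the centering is taken
#' from the sign of z about the current phosphorus mean, so the operation is
#' idempotent.  The midplane is recomputed per frame by default (the
#' membrane drifts in NPT); set `per_frame = FALSE` to apply the first
#' frame's shift throughout.
#'
#' @param frames a [FrameSet-class].
#' @param phosphorus_idx indices of lipid phosphorus atoms.
#' @param per_frame recompute the midplane for every frame?
#' @return the centered [FrameSet-class].
#' @export
centerMembrane <- function(frames, phosphorus_idx, per_frame = TRUE) {
  if (length(phosphorus_idx) < 2L)
    stop("need phosphorus atoms in both leaflets to define the midplane")
  co <- frames@coords
  nf <- dim(co)[3]
  shift <- numeric(nf)
  for (k in seq_len(nf)) {
    z <- co[phosphorus_idx, 3, k]
    mid0 <- mean(z)                      # provisional split point
    up <- z > mid0
    if (!any(up) || all(up))
      stop("cannot separate leaflets: all phosphorus atoms on one side")
    shift[k] <- (mean(z[up]) + mean(z[!up])) / 2
  }
  if (!per_frame) shift[] <- shift[1]
  for (k in seq_len(nf)) co[, 3, k] <- co[, 3, k] - shift[k]
  initialize(frames, coords = co)
}

#' Assign lipids to leaflets
#'
#' Outer if the head-group phosphorus has z > 0 at the designated reference
#' frame, inner if z < 0 (membrane must be centered).  A phosphorus exactly
#' at z = 0 inherits the previous frame's label; with no previous frame this
#' is an error.
#'
#' @param atoms atom table.
#' @param frames centered [FrameSet-class].
#' @param frame reference frame index (default 1).
#' @return data.frame with `residue_id`, `subunit_id`, `species` and
#'   `leaflet` (`"outer"`/`"inner"`), one row per lipid.
#' @export
assignLeaflets <- function(atoms, frames, frame = 1L) {
  p <- .phosphorusIdx(atoms)
  if (!length(p)) stop("no lipid phosphorus atoms found")
  z <- frames@coords[p, 3, frame]
  leaflet <- ifelse(z > 0, "outer", ifelse(z < 0, "inner", NA))
  if (anyNA(leaflet)) {
    k <- frame - 1L
    while (k >= 1L && anyNA(leaflet)) {
      zprev <- frames@coords[p, 3, k]
      fix <- is.na(leaflet) & zprev != 0
      leaflet[fix] <- ifelse(zprev[fix] > 0, "outer", "inner")
      k <- k - 1L
    }
    if (anyNA(leaflet))
      stop("phosphorus exactly at z = 0 with no previous frame to decide")
  }
  data.frame(residue_id = atoms$residue_id[p],
             subunit_id = atoms$subunit_id[p],
             species = atoms$residue_name[p],
             leaflet = leaflet, stringsAsFactors = FALSE)
}

#' Unwrap a z trace across periodic boundaries
#'
#' Successive raw differences larger than half the box are corrected by
#' whole box lengths, assuming the true per-frame displacement is below
#' box_z/2.
#'
#' @param z raw (wrapped) z positions, Angstrom.
#' @param box_z box length along z: scalar or per-frame vector.
#' @return the continuous z trace.
#' @export
unwrapZ <- function(z, box_z) {
  n <- length(z)
  if (n < 2L) return(z)
  box_z <- rep_len(box_z, n)
  dz <- diff(z)
  dz <- dz - box_z[-1] * round(dz / box_z[-1])
  c(z[1], z[1] + cumsum(dz))
}

# unwrapped z traces for a set of atoms: n_idx x n_frames matrix
.unwrappedZ <- function(frames, idx) {
  z <- frames@coords[idx, 3, , drop = FALSE][, 1, , drop = TRUE]
  z <- matrix(z, nrow = length(idx))
  bz <- frames@box[, 3]
  t(apply(z, 1L, unwrapZ, box_z = bz))
}
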