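#' @import methods
NULL

#' FrameSet: an ordered set of coordinate frames
#'
#' Container for a coordinate trajectory: an `n_atoms x 3 x n_frames` array of
#' Cartesian coordinates (Angstrom), per-frame orthorhombic box edges and
#' strictly increasing frame times in nanoseconds.
#'
#' @slot coords numeric array, `n_atoms x 3 x n_frames` (Angstrom).
#' @slot box numeric matrix, `n_frames x 3` box edges (Angstrom).
#' @slot time numeric vector of frame times (ns), strictly increasing.
#'
#' @examples
#' xyz <- array(rnorm(10 * 3 * 2), c(10, 3, 2))
#' fs <- FrameSet(xyz, box = c(50, 50, 50), time = c(0, 1))
#' nFrames(fs)
#' @export
setClass("FrameSet",
  representation(coords = "array", box = "matrix", time = "numeric"))

setValidity("FrameSet", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be an n_atoms x 3 x n_frames array")
  nf <- d[3]
  if (nrow(object@box) != nf || ncol(object@box) != 3L)
    return("box must be an n_frames x 3 matrix")
  if (any(object@box <= 0)) return("box dimensions must be positive")
  if (length(object@time) != nf) return("time must have one entry per frame")
  if (nf > 1L && any(diff(object@time) <= 0))
    return("frame times must be strictly increasing")
  TRUE
})

#' Construct a FrameSet
#'
#' @param coords `n_atoms x 3 x n_frames` array, or an `n_atoms x 3` matrix
#'   for a single frame.
#' @param box length-3 box edges (recycled over frames) or `n_frames x 3`
#'   matrix, Angstrom.
#' @param time frame times in ns; defaults to `0, 1, 2, ...`.
#' @return A [FrameSet-class] object.
#' @export
FrameSet <- function(coords, box, time = NULL) {
  if (length(dim(coords)) == 2L)
    coords <- array(coords, c(dim(coords), 1L))
  nf <- dim(coords)[3]
  if (is.null(dim(box))) box <- matrix(box, nf, 3, byrow = TRUE)
  if (is.null(time)) time <- seq_len(nf) - 1
  new("FrameSet", coords = coords, box = box, time = as.numeric(time))
}

#' OccupancyGrid: a voxelised occupancy or relative-density map
#'
#' A regular 3-D grid over a rectangular region.  In `fraction_of_frames`
#' mode each voxel holds the fraction of analysed frames in which at least
#' one selected atom fell in the voxel (values in `[0, 1]`); in
#' `relative_to_bulk` mode each voxel holds the time-averaged number density
#' divided by the bulk density of the same species.
#'
#' @slot origin grid origin (corner of the first voxel), Angstrom.
#' @slot voxelEdge cubic voxel edge length, Angstrom.
#' @slot dims integer voxel counts along x, y, z.
#' @slot values 3-D array of voxel values.
#' @slot mode `"fraction_of_frames"` or `"relative_to_bulk"`.
#' @slot metadata named list (frame count, bulk density, contour level, ...).
#' @export
setClass("OccupancyGrid",
  representation(origin = "numeric", voxelEdge = "numeric",
                 dims = "integer", values = "array",
                 mode = "character", metadata = "list"))

setValidity("OccupancyGrid", function(object) {
  if (length(object@origin) != 3L) return("origin must be length 3")
  if (object@voxelEdge <= 0) return("voxelEdge must be positive")
  if (!identical(dim(object@values), object@dims))
    return("values array dimensions must equal dims")
  if (!object@mode %in% c("fraction_of_frames", "relative_to_bulk"))
    return("unknown normalization mode")
  if (object@mode == "fraction_of_frames" &&
      (any(object@values < 0) || any(object@values > 1)))
    return("fraction_of_frames values must lie in [0, 1]")
  TRUE
})

#' AqueductCylinder: the per-subunit analysis cylinder
#'
#' A membrane-normal cylinder of given radius whose axis passes through the
#' geometric centre (x, y) of the atoms lining the translocation pathway of
#' one subunit.  The z extent is tiled by half-open slabs of fixed thickness.
#' The axis can be recomputed per frame (the protein drifts in NPT) or fixed
#' at a reference frame.
#'
#' @slot subunit subunit label.
#' @slot liningAtoms integer indices of the lining-helix atoms defining the
#'   axis.
#' @slot radius cylinder radius, Angstrom (field convention: 13).
#' @slot slabThickness slab thickness, Angstrom (field convention: 2).
#' @slot zExtent length-2 z range covered by the slabs, Angstrom.
#' @slot perFrame logical; recompute the axis each frame?
#' @slot axisXY reference axis position (x, y) at the frame used to define
#'   the cylinder.
#' @export
setClass("AqueductCylinder",
  representation(subunit = "character", liningAtoms = "integer",
                 radius = "numeric", slabThickness = "numeric",
                 zExtent = "numeric", perFrame = "logical",
                 axisXY = "numeric"))

setValidity("AqueductCylinder", function(object) {
  if (object@radius <= 0) return("radius must be positive")
  if (object@slabThickness <= 0) return("slabThickness must be positive")
  if (length(object@zExtent) != 2L || diff(object@zExtent) <= 0)
    return("zExtent must be an increasing length-2 range")
  if (length(object@liningAtoms) < 1L)
    return("at least one lining atom is required")
  TRUE
})
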