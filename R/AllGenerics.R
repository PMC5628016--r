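#' @describeIn FrameSet-class number of frames
#' @param x a `FrameSet`
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @describeIn FrameSet-class number of atoms
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @describeIn FrameSet-class frame times in ns
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @describeIn FrameSet-class per-frame box edges (n_frames x 3)
#' @export
setGeneric("boxDims", function(x) standardGeneric("boxDims"))

#' @describeIn FrameSet-class coordinates of one frame (`n_atoms x 3`)
#' @param frame frame index
#' @export
setGeneric("frameCoords", function(x, frame) standardGeneric("frameCoords"))

#' @export
setMethod("nFrames", "FrameSet", function(x) dim(x@coords)[3])

#' @export
setMethod("nAtoms", "FrameSet", function(x) dim(x@coords)[1])

#' @export
setMethod("frameTimes", "FrameSet", function(x) x@time)

#' @export
setMethod("boxDims", "FrameSet", function(x) x@box)

#' @export
setMethod("frameCoords", "FrameSet", function(x, frame) {
  x@coords[, , frame, drop = FALSE][, , 1]
})

setMethod("show", "FrameSet", function(object) {
  cat("FrameSet:", nAtoms(object), "atoms x", nFrames(object), "frames\n")
  cat("  time: ", object@time[1], " .. ",
      object@time[length(object@time)], " ns\n", sep = "")
  cat("  box (frame 1): ", paste(sprintf("%.2f", object@box[1, ]),
                                 collapse = " x "), " A\n", sep = "")
})

#' @describeIn OccupancyGrid-class voxel values array
#' @param x an `OccupancyGrid`
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @export
setMethod("gridValues", "OccupancyGrid", function(x) x@values)

#' @describeIn OccupancyGrid-class grid metadata list
#' @export
setGeneric("gridMetadata", function(x) standardGeneric("gridMetadata"))

#' @export
setMethod("gridMetadata", "OccupancyGrid", function(x) x@metadata)

setMethod("show", "OccupancyGrid", function(object) {
  cat("OccupancyGrid (", object@mode, "): ",
      paste(object@dims, collapse = " x "), " voxels, edge ",
      object@voxelEdge, " A\n", sep = "")
  cat("  origin:", paste(sprintf("%.2f", object@origin), collapse = ", "),
      "A\n")
  cat("  value range: ", sprintf("%.4g .. %.4g", min(object@values),
                                 max(object@values)), "\n", sep = "")
})

setMethod("show", "AqueductCylinder", function(object) {
  cat("AqueductCylinder subunit ", object@subunit, ": radius ",
      object@radius, " A, slabs ", object@slabThickness, " A over z [",
      object@zExtent[1], ", ", object@zExtent[2], "] A (",
      if (object@perFrame) "per-frame axis" else "fixed axis", ")\n",
      sep = "")
})
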