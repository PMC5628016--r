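# Generic occupancy-grid engine shared by all density analyses.  Voxels are
# cubic with half-open bounds [low, high) on each axis.

# voxel index triple for coordinates within the region, NA outside
.voxelIndex <- function(xyz, origin, edge, dims) {
  i <- floor((sweep(xyz, 2, origin)) / edge) + 1
  ok <- i[, 1] >= 1 & i[, 1] <= dims[1] &
        i[, 2] >= 1 & i[, 2] <= dims[2] &
        i[, 3] >= 1 & i[, 3] <= dims[3]
  i[!ok, ] <- NA
  storage.mode(i) <- "integer"
  i
}

#' Occupancy/density grid over a trajectory
#'
#' In `fraction_of_frames` mode a voxel's value is the fraction of frames in
#' which at least one selected atom occupies it.  In `relative_to_bulk` mode
#' the voxel's time-averaged number density is divided by the bulk density
#' of the same species, estimated from voxels at least `bulk_distance`
#' (default 20 Angstrom) from any protein atom at the reference frame.
#'
#' @param frames a [FrameSet-class].
#' @param selection integer indices of the atoms to map.
#' @param voxel_edge cubic voxel edge, Angstrom.
#' @param region 3 x 2 matrix of axis ranges (rows x, y, z); default the
#'   bounding box of the selection over all frames, expanded by one voxel.
#' @param mode `"fraction_of_frames"` or `"relative_to_bulk"`.
#' @param protein_idx protein atom indices (required for bulk estimation).
#' @param bulk_distance distance from protein defining bulk, Angstrom.
#' @param reference_frame frame used to locate the protein for the bulk
#'   region.
#' @return an [OccupancyGrid-class].
#' @export
occupancyGrid <- function(frames, selection, voxel_edge = 1,
                          region = NULL, mode = "fraction_of_frames",
                          protein_idx = NULL, bulk_distance = 20,
                          reference_frame = 1L) {
  stopifnot(voxel_edge > 0)
  mode <- match.arg(mode, c("fraction_of_frames", "relative_to_bulk"))
  nf <- nFrames(frames)
  if (!length(selection)) {
    warning("empty selection: returning an all-zero grid")
    if (is.null(region)) region <- rbind(c(0, 1), c(0, 1), c(0, 1))
  }
  if (is.null(region)) {
    co <- frames@coords[selection, , , drop = FALSE]
    region <- t(apply(co, 2, range))
    region[, 1] <- region[, 1] - voxel_edge
    region[, 2] <- region[, 2] + voxel_edge
  }
  region <- rbind(region)
  origin <- region[, 1]
  dims <- as.integer(pmax(1, ceiling((region[, 2] - origin) / voxel_edge)))
  counts <- array(0, dims)     # occupied-frame counts or atom-frame counts
  for (k in seq_len(nf)) {
    if (!length(selection)) break
    xyz <- frames@coords[selection, , k, drop = FALSE][, , 1]
    xyz <- matrix(xyz, ncol = 3)
    vi <- .voxelIndex(xyz, origin, voxel_edge, dims)
    vi <- vi[stats::complete.cases(vi), , drop = FALSE]
    if (!nrow(vi)) next
    if (mode == "fraction_of_frames") vi <- unique(vi)
    flat <- (vi[, 3] - 1L) * dims[1] * dims[2] + (vi[, 2] - 1L) * dims[1] +
      vi[, 1]
    tab <- tabulate(flat, nbins = prod(dims))
    counts <- counts + array(tab, dims)
  }
  md <- list(n_frames = nf, voxel_edge = voxel_edge)
  if (mode == "fraction_of_frames") {
    values <- counts / nf
  } else {
    dens <- counts / nf / voxel_edge^3       # mean number density per voxel
    if (is.null(protein_idx) || !length(protein_idx))
      stop("relative_to_bulk mode needs protein_idx to locate the bulk")
    centers <- .voxelCenters(origin, voxel_edge, dims)
    prot <- matrix(frames@coords[protein_idx, , reference_frame], ncol = 3)
    dmin <- minDistToSet(centers, prot, box = frames@box[reference_frame, ])
    bulk <- dmin >= bulk_distance
    if (!any(bulk))
      stop("no bulk region: no voxel center is >= ", bulk_distance,
           " A from the protein (box too small)")
    bulk_density <- mean(dens[array(bulk, dims)])
    if (bulk_density <= 0)
      stop("bulk density is zero; cannot normalise relative to bulk")
    values <- dens / bulk_density
    md$bulk_density <- bulk_density
    md$bulk_distance <- bulk_distance
  }
  new("OccupancyGrid", origin = origin, voxelEdge = voxel_edge,
      dims = dims, values = values, mode = mode, metadata = md)
}

# n_voxel x 3 matrix of voxel center coordinates, x fastest
.voxelCenters <- function(origin, edge, dims) {
  gx <- origin[1] + (seq_len(dims[1]) - 0.5) * edge
  gy <- origin[2] + (seq_len(dims[2]) - 0.5) * edge
  gz <- origin[3] + (seq_len(dims[3]) - 0.5) * edge
  as.matrix(expand.grid(x = gx, y = gy, z = gz))
}
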