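# Membrane deformation metrics near the protein: how many phosphate groups
# penetrate the hydrophobic core, where they sit along z, and their 3-D
# density relative to bulk.

#' Per-frame count of phosphates inside the membrane core near the protein
#'
#' Counts lipid head-group phosphorus atoms with `|z| <= h/2` (core slab of
#' thickness `h`) that lie within `shell_radius` of any protein atom
#' (minimum atom-atom distance; boundaries inclusive).  The membrane must be
#' centered at z = 0.
#'
#' @param atoms atom table.
#' @param frames centered [FrameSet-class].
#' @param core_half_thickness h/2, Angstrom (10 or 12.5 for the 20/25
#'   Angstrom core definitions).
#' @param shell_radius distance from the protein surface, Angstrom.
#' @return integer vector, one count per frame.
#' @export
corePhosphateCount <- function(atoms, frames, core_half_thickness = 10,
                               shell_radius = 10) {
  p <- .phosphorusIdx(atoms)
  prot <- which(atoms$role == "protein")
  nf <- nFrames(frames)
  out <- integer(nf)
  for (k in seq_len(nf)) {
    xyz <- frameCoords(frames, k)
    pz <- xyz[p, 3]
    cand <- p[abs(pz) <= core_half_thickness]
    if (!length(cand)) next
    d <- minDistToSet(xyz[cand, , drop = FALSE],
                      xyz[prot, , drop = FALSE], box = frames@box[k, ])
    out[k] <- sum(d <= shell_radius)
  }
  out
}

#' z histogram of shell phosphates
#'
#' Bins the z positions of lipid phosphorus atoms within `shell_radius` of
#' the protein into half-open bins `[z, z + bin_width)`.  Over a window of
#' frames the per-frame histograms are averaged.
#'
#' @param atoms atom table.
#' @param frames centered [FrameSet-class].
#' @param window frame indices (default: all frames).
#' @param shell_radius shell distance from the protein, Angstrom; `Inf`
#'   uses every lipid phosphorus.
#' @param bin_width bin width, Angstrom.
#' @param z_range length-2 histogram range; default covers the box.
#' @return data.frame with `z_lower`, `z_upper`, `count` (mean per frame).
#' @export
phosphateZHistogram <- function(atoms, frames, window = NULL,
                                shell_radius = 10, bin_width = 1,
                                z_range = NULL) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (is.null(window)) window <- seq_len(nFrames(frames))
  p <- .phosphorusIdx(atoms)
  prot <- which(atoms$role == "protein")
  if (is.null(z_range)) {
    half <- max(frames@box[window, 3]) / 2
    z_range <- c(-half, half)
  }
  breaks <- seq(floor(z_range[1] / bin_width) * bin_width,
                ceiling(z_range[2] / bin_width) * bin_width, by = bin_width)
  acc <- numeric(length(breaks) - 1L)
  for (k in window) {
    xyz <- frameCoords(frames, k)
    keep <- p
    if (is.finite(shell_radius) && length(prot)) {
      d <- minDistToSet(xyz[p, , drop = FALSE], xyz[prot, , drop = FALSE],
                        box = frames@box[k, ])
      keep <- p[d <= shell_radius]
    }
    z <- xyz[keep, 3]
    idx <- floor((z - breaks[1]) / bin_width) + 1L   # half-open [lo, hi)
    idx <- idx[idx >= 1L & idx <= length(acc)]
    acc <- acc + tabulate(idx, nbins = length(acc))
  }
  data.frame(z_lower = breaks[-length(breaks)], z_upper = breaks[-1],
             count = acc / length(window))
}

#' Shell phosphate (or other species) density map relative to bulk
#'
#' Time-averaged number-density grid of the selected species, normalised to
#' its bulk density and masked to the shell within `shell_radius` of the
#' protein (reference frame).  The contour level customarily drawn on such
#' maps (a stated fraction of bulk) is recorded in the metadata.
#'
#' @param atoms atom table.
#' @param frames [FrameSet-class].
#' @param selection atom indices to map (default: lipid phosphorus).
#' @param voxel_edge voxel size, Angstrom.
#' @param shell_radius shell mask distance, Angstrom (`Inf`: no mask).
#' @param bulk_threshold_fraction contour level as fraction of bulk
#'   density; recorded in the map metadata.
#' @param bulk_distance distance from protein defining bulk, Angstrom.
#' @param region optional 3 x 2 region matrix.
#' @return an [OccupancyGrid-class] in `relative_to_bulk` mode; metadata
#'   holds `contour_level` and `bulk_threshold_fraction`.
#' @export
shellDensityMap <- function(atoms, frames, selection = NULL, voxel_edge = 1,
                            shell_radius = 10,
                            bulk_threshold_fraction = 0.075,
                            bulk_distance = 20, region = NULL) {
  if (is.null(selection)) selection <- .phosphorusIdx(atoms)
  prot <- which(atoms$role == "protein")
  if (!length(selection)) {
    warning("empty species selection: zero map")
    g <- suppressWarnings(
      occupancyGrid(frames, integer(0), voxel_edge, region = region))
    g@metadata$bulk_threshold_fraction <- bulk_threshold_fraction
    return(g)
  }
  g <- occupancyGrid(frames, selection, voxel_edge, region = region,
                     mode = "relative_to_bulk", protein_idx = prot,
                     bulk_distance = bulk_distance)
  if (is.finite(shell_radius) && length(prot)) {
    centers <- .voxelCenters(g@origin, g@voxelEdge, g@dims)
    protxyz <- matrix(frames@coords[prot, , 1], ncol = 3)
    dmin <- minDistToSet(centers, protxyz, box = frames@box[1, ])
    mask <- array(dmin <= shell_radius, g@dims)
    v <- g@values; v[!mask] <- 0
    g@values <- v
    g@metadata$shell_radius <- shell_radius
  }
  g@metadata$bulk_threshold_fraction <- bulk_threshold_fraction
  # values are already density/bulk, so the contour sits at the fraction
  g@metadata$contour_level <- bulk_threshold_fraction
  g
}
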