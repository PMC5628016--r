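# The per-subunit aqueduct cylinder and everything measured inside it:
# hydration, phosphate occupancy, lipid z-traces and flip-flop detection.

#' Define the aqueduct cylinder of each subunit
#'
#' The axis is perpendicular to the membrane and passes through the
#' geometric centre (x, y) of the atoms of the lining helices; by default
#' it is recomputed per frame because the protein drifts in NPT.
#'
#' @param atoms atom table.
#' @param frames [FrameSet-class] (frame 1 is the reference).
#' @param lining_residue_ranges list of integer residue-id ranges of the
#'   lining helices (e.g. [syntheticLiningRanges()]).
#' @param radius cylinder radius, Angstrom (field convention 13).
#' @param slab_thickness slab thickness, Angstrom (field convention 2).
#' @param z_extent length-2 z range tiled by the slabs.
#' @param subunits subunit labels; default: all subunits containing lining
#'   residues.
#' @param per_frame recompute the axis each frame?
#' @return named list of [AqueductCylinder-class], one per subunit.
#' @export
defineAqueduct <- function(atoms, frames, lining_residue_ranges,
                           radius = 13, slab_thickness = 2,
                           z_extent = c(-20, 20), subunits = NULL,
                           per_frame = TRUE) {
  resids <- unlist(lining_residue_ranges, use.names = FALSE)
  sel <- atoms$role == "protein" & atoms$residue_id %in% resids
  if (!any(sel))
    stop("no lining-helix atoms found for residue range(s) ",
         paste(range(resids), collapse = ".."))
  if (is.null(subunits)) subunits <- unique(atoms$subunit_id[sel])
  out <- list()
  for (s in subunits) {
    idx <- which(sel & atoms$subunit_id == s)
    if (!length(idx))
      stop("no lining-helix atoms in subunit ", s, " for residue range(s) ",
           paste(range(resids), collapse = ".."))
    axy <- colMeans(matrix(frames@coords[idx, 1:2, 1], ncol = 2))
    out[[s]] <- new("AqueductCylinder", subunit = s,
                    liningAtoms = as.integer(idx), radius = radius,
                    slabThickness = slab_thickness, zExtent = z_extent,
                    perFrame = per_frame, axisXY = axy)
  }
  out
}

# cylinder axis (x, y) at one frame
.cylinderAxis <- function(cyl, frames, k) {
  if (!cyl@perFrame) return(cyl@axisXY)
  colMeans(matrix(frames@coords[cyl@liningAtoms, 1:2, k], ncol = 2))
}

# radial distance of coordinates to the cylinder axis at one frame
.radialDist <- function(cyl, frames, k, xyz) {
  ax <- .cylinderAxis(cyl, frames, k)
  sqrt((xyz[, 1] - ax[1])^2 + (xyz[, 2] - ax[2])^2)
}

#' Per-slab hydration profile of an aqueduct
#'
#' Time-averaged count of water oxygen atoms per half-open 2-Angstrom slab
#' of the cylinder over a window of frames.
#'
#' @param atoms atom table.
#' @param frames centered [FrameSet-class].
#' @param cylinder an [AqueductCylinder-class].
#' @param window frame indices (default: all).
#' @return data.frame with `z_lower`, `z_upper`, `mean_count`.
#' @export
hydrationProfile <- function(atoms, frames, cylinder, window = NULL) {
  if (is.null(window)) window <- seq_len(nFrames(frames))
  if (any(window < 1L) || any(window > nFrames(frames)))
    stop("window outside the trajectory (1..", nFrames(frames), ")")
  watO <- which(atoms$role == "water" & atoms$element == "O")
  lo <- seq(cylinder@zExtent[1], cylinder@zExtent[2] - cylinder@slabThickness,
            by = cylinder@slabThickness)
  acc <- numeric(length(lo))
  for (k in window) {
    if (!length(watO)) break
    xyz <- matrix(frames@coords[watO, , k], ncol = 3)
    r <- .radialDist(cylinder, frames, k, xyz)
    z <- xyz[r <= cylinder@radius, 3]
    idx <- floor((z - lo[1]) / cylinder@slabThickness) + 1L  # [lo, hi)
    idx <- idx[idx >= 1L & idx <= length(lo)]
    acc <- acc + tabulate(idx, nbins = length(lo))
  }
  data.frame(z_lower = lo, z_upper = lo + cylinder@slabThickness,
             mean_count = acc / length(window))
}

#' Phosphate count time series inside an aqueduct core
#'
#' Per frame, the number of lipid phosphorus atoms radially inside the
#' cylinder with `|z| <= core_half_thickness` (the 20-Angstrom-thick core),
#' with a 20-sample moving average and a normalised count histogram over a
#' window.
#'
#' @param atoms atom table.
#' @param frames centered [FrameSet-class].
#' @param cylinder an [AqueductCylinder-class].
#' @param core_half_thickness Angstrom (default 10).
#' @param ma_window moving-average length in samples (default 20).
#' @param hist_window frame indices for the histogram (default: all).
#' @return list with `count` (per frame), `moving_average`, and
#'   `histogram` (data.frame `count`, `probability`, summing to 1).
#' @export
aqueductPhosphateSeries <- function(atoms, frames, cylinder,
                                    core_half_thickness = 10,
                                    ma_window = 20, hist_window = NULL) {
  p <- .phosphorusIdx(atoms)
  nf <- nFrames(frames)
  cnt <- integer(nf)
  for (k in seq_len(nf)) {
    xyz <- matrix(frames@coords[p, , k], ncol = 3)
    r <- .radialDist(cylinder, frames, k, xyz)
    cnt[k] <- sum(r <= cylinder@radius & abs(xyz[, 3]) <= core_half_thickness)
  }
  if (is.null(hist_window)) hist_window <- seq_len(nf)
  tab <- table(cnt[hist_window])
  hist <- data.frame(count = as.integer(names(tab)),
                     probability = as.numeric(tab) / length(hist_window))
  list(count = cnt, moving_average = movingAverage(cnt, ma_window),
       histogram = hist)
}

#' Trace lipid phosphorus atoms through an aqueduct
#'
#' One z-trace per lipid whose phosphorus ever enters the cylinder
#' radially, with an inside-cylinder flag per frame, plus a z-frequency
#' histogram (1-Angstrom bins) accumulated over inside-cylinder samples
#' only.
#'
#' @param atoms atom table.
#' @param frames centered [FrameSet-class].
#' @param cylinder an [AqueductCylinder-class].
#' @param bin_width histogram bin width, Angstrom.
#' @return list with `traces` (named list of data.frames `time`, `z`,
#'   `inside`, plus attributes `species`/`lipid_id`) and `histogram`
#'   (data.frame `z_lower`, `z_upper`, `count`).
#' @export
traceLipids <- function(atoms, frames, cylinder, bin_width = 1) {
  p <- .phosphorusIdx(atoms)
  nf <- nFrames(frames)
  zu <- .unwrappedZ(frames, p)
  inside <- matrix(FALSE, length(p), nf)
  for (k in seq_len(nf)) {
    xyz <- matrix(frames@coords[p, , k], ncol = 3)
    inside[, k] <- .radialDist(cylinder, frames, k, xyz) <= cylinder@radius
  }
  ever <- which(rowSums(inside) > 0)
  traces <- list()
  for (i in ever) {
    tr <- data.frame(time = frameTimes(frames), z = zu[i, ],
                     inside = inside[i, ])
    attr(tr, "lipid_id") <- atoms$residue_id[p[i]]
    attr(tr, "species") <- atoms$residue_name[p[i]]
    attr(tr, "subunit") <- cylinder@subunit
    traces[[as.character(atoms$residue_id[p[i]])]] <- tr
  }
  zin <- zu[inside]
  lo <- floor(min(c(zin, -1)) / bin_width) * bin_width
  hi <- ceiling(max(c(zin, 1)) / bin_width) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  idx <- floor((zin - lo) / bin_width) + 1L
  idx <- idx[idx >= 1L & idx <= length(breaks) - 1L]
  hist <- data.frame(z_lower = breaks[-length(breaks)],
                     z_upper = breaks[-1],
                     count = tabulate(idx, nbins = length(breaks) - 1L))
  list(traces = traces, histogram = hist)
}

#' Detect lipid flip-flop events from z-traces
#'
#' A full event is a trace that leaves one leaflet zone
#' (`|z| >= leaflet_zone`), and reaches the opposite leaflet zone; the
#' event completes at the first frame inside the far zone.  Returning to
#' the entry zone before completion cancels the attempt (hysteresis, so
#' thermal recrossings are never double counted).  A trace that has
#' reached the midplane band (`|z| <= midplane_band`) when the trajectory
#' ends, without completing or cancelling, is a half event.  Events from
#' the inner leaflet are floppings, from the outer leaflet flippings.  A
#' lipid may produce several sequential events.  The transit must visit
#' the cylinder interior (`inside` flag) at least once within the core
#' region, so crossings far from the aqueduct are not attributed to it.
#'
#' @param traces the `traces` element of [traceLipids()].
#' @param leaflet_zone unsigned z bound of the leaflet zones, Angstrom.
#' @param midplane_band unsigned z half-width of the midplane band.
#' @param core_half_thickness z half-width within which the in-cylinder
#'   visit is required.
#' @return data.frame of events: `lipid_id`, `species`, `subunit`,
#'   `class`, `t_enter`, `t_exit`, `z_min`, `z_max`.
#' @export
detectFlipEvents <- function(traces, leaflet_zone = 15, midplane_band = 5,
                             core_half_thickness = 10) {
  out <- data.frame(lipid_id = integer(0), species = character(0),
                    subunit = character(0), class = character(0),
                    t_enter = numeric(0), t_exit = numeric(0),
                    z_min = numeric(0), z_max = numeric(0),
                    stringsAsFactors = FALSE)
  for (tr in traces) {
    z <- tr$z; tm <- tr$time; ins <- tr$inside
    zone <- ifelse(z >= leaflet_zone, 1L, ifelse(z <= -leaflet_zone, -1L,
                                                 0L))
    side <- 0L           # leaflet zone currently anchoring the lipid
    t_enter <- NA_real_; i_enter <- NA_integer_
    reached_band <- FALSE
    emit <- function(class, i_exit) {
      seg <- i_enter:i_exit
      if (!any(ins[seg] & abs(z[seg]) <= core_half_thickness))
        return(FALSE)   # transit never visited the aqueduct core
      out[nrow(out) + 1L, ] <<- list(attr(tr, "lipid_id"),
                                     attr(tr, "species"),
                                     attr(tr, "subunit"), class,
                                     t_enter, tm[i_exit],
                                     min(z[seg]), max(z[seg]))
      TRUE
    }
    for (i in seq_along(z)) {
      if (zone[i] != 0L) {
        if (side == 0L) {
          side <- zone[i]
        } else if (zone[i] == -side && !is.na(t_enter)) {
          # reached the far leaflet zone: full event completes here
          cls <- if (side == -1L) "full_flop" else "full_flip"
          emit(cls, i)
          side <- zone[i]; t_enter <- NA_real_; reached_band <- FALSE
        } else {
          # back in (or still in) the entry zone: cancel any attempt
          t_enter <- NA_real_; reached_band <- FALSE
        }
      } else if (side != 0L) {
        if (is.na(t_enter)) { t_enter <- tm[i]; i_enter <- i }
        if (abs(z[i]) <= midplane_band) reached_band <- TRUE
      }
    }
    if (!is.na(t_enter) && reached_band) {
      cls <- if (side == -1L) "half_flop" else "half_flip"
      emit(cls, length(z))
    }
  }
  out
}

#' Per-slab dwell times of a transit
#'
#' Time spent by a trace in each cylinder slab between two times, using
#' frame durations (time to the next frame; the last frame reuses the
#' previous spacing).
#'
#' @param trace one trace from [traceLipids()].
#' @param t_enter,t_exit event window (ns).
#' @param z_extent,slab_thickness slab layout, Angstrom.
#' @return data.frame `z_lower`, `z_upper`, `dwell_ns`.
#' @export
eventSlabDwell <- function(trace, t_enter, t_exit, z_extent = c(-20, 20),
                           slab_thickness = 2) {
  lo <- seq(z_extent[1], z_extent[2] - slab_thickness, by = slab_thickness)
  dur <- .frameDurations(trace$time)
  keep <- trace$time >= t_enter & trace$time <= t_exit
  idx <- floor((trace$z[keep] - lo[1]) / slab_thickness) + 1L
  ok <- idx >= 1L & idx <= length(lo)
  dwell <- numeric(length(lo))
  for (j in which(ok)) dwell[idx[j]] <- dwell[idx[j]] + dur[keep][j]
  data.frame(z_lower = lo, z_upper = lo + slab_thickness, dwell_ns = dwell)
}
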