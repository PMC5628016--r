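# Ion permeation: full-crossing detection through the aqueduct, summary
# bookkeeping, and conversion of an applied uniform electric field to the
# transmembrane potential it imposes.

#' Unwrapped z traces of ions
#'
#' @param atoms atom table.
#' @param frames [FrameSet-class].
#' @param species ion species to trace (element labels, e.g. `"Na"`).
#' @return named list of data.frames `time`, `z`, `x`, `y` with attributes
#'   `ion_id` and `species`.  z is unwrapped across the periodic boundary.
#' @export
ionTraces <- function(atoms, frames, species = c("Na", "Cl")) {
  idx <- which(atoms$role == "ion" & atoms$element %in% species)
  if (!length(idx)) return(list())
  zu <- .unwrappedZ(frames, idx)
  out <- list()
  for (j in seq_along(idx)) {
    i <- idx[j]
    tr <- data.frame(time = frameTimes(frames), z = zu[j, ],
                     x = frames@coords[i, 1, ], y = frames@coords[i, 2, ])
    attr(tr, "ion_id") <- atoms$residue_id[i]
    attr(tr, "species") <- atoms$element[i]
    out[[as.character(atoms$residue_id[i])]] <- tr
  }
  out
}

#' Detect full ion permeation events through an aqueduct
#'
#' An event is recorded when an ion moves from beyond one boundary plane
#' (`|z| >= boundary`) to beyond the opposite one; it completes at the
#' first frame past the far plane.  Returning behind the entry plane
#' before completion cancels the attempt (hysteresis), so an ion that
#' reverses never produces a spurious event.  Radial confinement to the
#' cylinder is enforced only while the ion crosses the core region
#' (`|z| <= core_half_thickness`): ions may approach through the wide
#' vestibules outside the cylinder.  A periodic-boundary wrap is never a
#' permeation because detection runs on unwrapped z.
#'
#' @param traces output of [ionTraces()].
#' @param cylinders named list of [AqueductCylinder-class] (one per
#'   subunit); the subunit whose cylinder contains the core crossing is
#'   assigned to the event.
#' @param frames the [FrameSet-class] the traces came from (for the
#'   per-frame cylinder axis).
#' @param boundary unsigned boundary-plane z, Angstrom (default 15).
#' @param core_half_thickness core half-width for radial confinement.
#' @return data.frame of events: `ion_id`, `species`, `direction`
#'   (`inward` = extracellular z > 0 to intracellular), `subunit`,
#'   `t_start`, `t_complete`, `duration`.
#' @export
detectIonPermeations <- function(traces, cylinders, frames,
                                 boundary = 15, core_half_thickness = 10) {
  out <- data.frame(ion_id = integer(0), species = character(0),
                    direction = character(0), subunit = character(0),
                    t_start = numeric(0), t_complete = numeric(0),
                    duration = numeric(0), stringsAsFactors = FALSE)
  for (tr in traces) {
    z <- tr$z; tm <- tr$time
    zone <- ifelse(z >= boundary, 1L, ifelse(z <= -boundary, -1L, 0L))
    side <- 0L; i_start <- NA_integer_
    for (i in seq_along(z)) {
      if (zone[i] != 0L) {
        if (side != 0L && zone[i] == -side && !is.na(i_start)) {
          # candidate crossing: check radial confinement in the core
          seg <- i_start:i
          core <- seg[abs(z[seg]) <= core_half_thickness]
          sub <- .coreSubunit(tr, core, cylinders, frames)
          if (!is.na(sub)) {
            t_start <- tm[i_start]
            out[nrow(out) + 1L, ] <- list(attr(tr, "ion_id"),
                                          attr(tr, "species"),
                                          if (side > 0) "inward" else
                                            "outward", sub, t_start,
                                          tm[i], tm[i] - t_start)
          }
        }
        side <- zone[i]; i_start <- NA_integer_
      } else if (side != 0L && is.na(i_start)) {
        i_start <- i                      # left the entry plane here
      }
    }
  }
  out
}

# subunit whose cylinder radially contains the ion for every core frame;
# NA if none does
.coreSubunit <- function(tr, core, cylinders, frames) {
  if (!length(core)) return(NA_character_)
  for (s in names(cylinders)) {
    cyl <- cylinders[[s]]
    ok <- TRUE
    for (i in core) {
      ax <- .cylinderAxis(cyl, frames, i)
      r <- sqrt((tr$x[i] - ax[1])^2 + (tr$y[i] - ax[2])^2)
      if (r > cyl@radius) { ok <- FALSE; break }
    }
    if (ok) return(s)
  }
  NA_character_
}

#' Summarise permeation events
#'
#' @param events output of [detectIonPermeations()].
#' @return list with `table` (counts per species x direction x subunit)
#'   and `completion_times` (sorted, ns).
#' @export
permeationSummary <- function(events) {
  if (!nrow(events)) {
    tab <- data.frame(species = character(0), direction = character(0),
                      subunit = character(0), n = integer(0))
  } else {
    agg <- stats::aggregate(list(n = events$ion_id),
                            by = list(species = events$species,
                                      direction = events$direction,
                                      subunit = events$subunit), FUN = length)
    tab <- agg[order(agg$species, agg$direction, agg$subunit), ,
               drop = FALSE]
    row.names(tab) <- NULL
  }
  list(table = tab, completion_times = sort(events$t_complete))
}

#' Transmembrane potential of an applied uniform field
#'
#' A field of magnitude E applied along -z (extracellular to intracellular)
#' over a box of height Lz imposes a potential of -E * Lz (inside negative
#' relative to outside).
#'
#' @param E field magnitude, mV/Angstrom.
#' @param Lz box height along the field, Angstrom.
#' @return potential in mV (negative for E > 0).
#' @export
appliedVoltage <- function(E, Lz) {
  if (any(Lz <= 0)) stop("Lz must be positive")
  -E * Lz
}
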