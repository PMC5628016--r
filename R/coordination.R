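# Coordination statistics at the 3-Angstrom cutoff: per-frame donor counts
# by class around an ion or a lipid head group, event-averaged coordination
# numbers, head-group coordination histograms, and per-residue coordination
# ratios (coordinations per ns).

# frame durations: time to the next frame; the last frame reuses the
# previous spacing
.frameDurations <- function(time) {
  n <- length(time)
  if (n == 1L) return(1)
  d <- diff(time)
  c(d, d[n - 1L])
}

# donor-atom index sets by class
.donorSets <- function(atoms) {
  list(water_O = which(atoms$role == "water" & atoms$element == "O"),
       protein_O_N = which(atoms$role == "protein" &
                             atoms$element %in% c("O", "N")),
       lipid_O_N = which(atoms$role %in% c("lipid_head", "lipid_tail") &
                           atoms$element %in% c("O", "N")))
}

#' Per-frame coordination counts around an ion or lipid head group
#'
#' Counts donor atoms (water oxygens; protein oxygens/nitrogens; lipid
#' oxygens/nitrogens) within the cutoff of the centre: for an ion, the ion
#' position; for a lipid, any of its head-group P/O/N atoms (each donor
#' atom counted once per frame).
#'
#' @param atoms atom table.
#' @param frames [FrameSet-class].
#' @param entity list(`kind` = "ion"/"lipid", `residue_id`, `subunit_id`).
#' @param cutoff coordination cutoff, Angstrom (field convention 3).
#' @return data.frame `time`, `water_O`, `protein_O_N`, `lipid_O_N`, with
#'   attributes `entity` and `cutoff`.
#' @export
coordinationSeries <- function(atoms, frames, entity, cutoff = 3) {
  donors <- .donorSets(atoms)
  if (entity$kind == "ion") {
    ctr <- which(atoms$role %in% c("ion", "bound_cation") &
                   atoms$residue_id == entity$residue_id &
                   atoms$subunit_id == entity$subunit_id)
  } else {
    own <- which(atoms$residue_id == entity$residue_id &
                   atoms$subunit_id == entity$subunit_id)
    ctr <- own[atoms$role[own] == "lipid_head" &
                 atoms$element[own] %in% c("P", "O", "N")]
    # a lipid's own atoms are not donors to itself
    donors$lipid_O_N <- setdiff(donors$lipid_O_N, own)
  }
  if (!length(ctr)) stop("entity not found: ", entity$residue_id)
  nf <- nFrames(frames)
  out <- data.frame(time = frameTimes(frames), water_O = integer(nf),
                    protein_O_N = integer(nf), lipid_O_N = integer(nf))
  for (k in seq_len(nf)) {
    xyz <- frameCoords(frames, k)
    cxyz <- xyz[ctr, , drop = FALSE]
    for (cls in names(donors)) {
      di <- donors[[cls]]
      if (!length(di)) next
      d <- pairDistances(xyz[di, , drop = FALSE], cxyz,
                         box = frames@box[k, ])
      out[[cls]][k] <- sum(apply(d <= cutoff, 1L, any))
    }
  }
  attr(out, "entity") <- entity
  attr(out, "cutoff") <- cutoff
  out
}

#' Event-averaged coordination number and donor-class split
#'
#' The mean coordination over an event is the duration-weighted total
#' number of coordinations divided by the event duration; the split gives
#' each donor class's percentage of all coordinations (summing to 100).
#'
#' @param series a [coordinationSeries()] result.
#' @param event_window length-2 time range (ns) of the event.
#' @return list with `mean`, `percent` (named, by donor class) and
#'   `total_by_class`.
#' @export
eventAverageCoordination <- function(series,
                                     event_window = range(series$time)) {
  keep <- series$time >= event_window[1] & series$time <= event_window[2]
  if (sum(keep) == 0 || diff(event_window) <= 0)
    stop("zero-length event window")
  dur <- .frameDurations(series$time)[keep]
  cls <- c("water_O", "protein_O_N", "lipid_O_N")
  totals <- vapply(cls, function(cc) sum(series[[cc]][keep] * dur), 0)
  total_time <- sum(dur)
  mean_coord <- sum(totals) / total_time
  pct <- if (sum(totals) > 0) 100 * totals / sum(totals) else totals * 0
  list(mean = mean_coord, percent = pct, total_by_class = totals)
}

#' Head-group coordination histogram during an event
#'
#' Normalised probability histogram of the per-frame donor count (default:
#' protein O/N donors) over the event, and the fraction of time the count
#' is at least `at_least`.
#'
#' @param series a [coordinationSeries()] result.
#' @param event_window length-2 time range (ns).
#' @param donor donor class column.
#' @param at_least threshold for the reported time fraction (default 2).
#' @return list with `histogram` (data.frame `count`, `probability`,
#'   summing to 1) and `fraction_at_least`.
#' @export
headgroupCoordinationHistogram <- function(series,
                                           event_window =
                                             range(series$time),
                                           donor = "protein_O_N",
                                           at_least = 2L) {
  keep <- series$time >= event_window[1] & series$time <= event_window[2]
  cnt <- series[[donor]][keep]
  dur <- .frameDurations(series$time)[keep]
  tab <- tapply(dur, factor(cnt), sum)
  hist <- data.frame(count = as.integer(names(tab)),
                     probability = as.numeric(tab) / sum(dur))
  list(histogram = hist,
       fraction_at_least = sum(dur[cnt >= at_least]) / sum(dur))
}

#' Per-residue coordination ratio (coordinations per ns) by lipid species
#'
#' For each protein residue and lipid species: the total number of donor
#' O/N atoms that residue places within the cutoff of head-group P/O/N
#' atoms of lipids of that species, summed over frames weighted by frame
#' duration, divided by the window duration.  Head groups can be
#' restricted to the aqueduct cylinder.
#'
#' @param atoms atom table.
#' @param frames [FrameSet-class].
#' @param species lipid species vector (default POPC and POPS).
#' @param window frame indices (default: all).
#' @param cylinder optional [AqueductCylinder-class] restricting the head
#'   groups considered.
#' @param cutoff coordination cutoff, Angstrom.
#' @return data.frame `subunit_id`, `residue_id`, `residue_name`, one
#'   `ratio_<species>` column per species (coordinations/ns).
#' @export
coordinationRatio <- function(atoms, frames, species = c("POPC", "POPS"),
                              window = NULL, cylinder = NULL, cutoff = 3) {
  if (is.null(window)) window <- seq_len(nFrames(frames))
  tm <- frameTimes(frames)
  dur <- .frameDurations(tm)[window]
  total_time <- sum(dur)
  if (total_time <= 0) stop("window duration must be positive")
  prot <- .proteinPolarIdx(atoms)
  res_key <- paste(atoms$subunit_id[prot], atoms$residue_id[prot],
                   atoms$residue_name[prot], sep = "\r")
  keys <- unique(res_key)
  totals <- matrix(0, length(keys), length(species),
                   dimnames = list(keys, species))
  for (w in seq_along(window)) {
    k <- window[w]
    xyz <- frameCoords(frames, k)
    for (sp in species) {
      hg <- which(atoms$role == "lipid_head" &
                    atoms$residue_name == sp &
                    atoms$element %in% c("P", "O", "N"))
      if (!length(hg)) next
      if (!is.null(cylinder)) {
        hxyz <- xyz[hg, , drop = FALSE]
        r <- .radialDist(cylinder, frames, k, hxyz)
        inz <- hxyz[, 3] >= cylinder@zExtent[1] &
          hxyz[, 3] <= cylinder@zExtent[2]
        hg <- hg[r <= cylinder@radius & inz]
        if (!length(hg)) next
      }
      d <- pairDistances(xyz[prot, , drop = FALSE],
                         xyz[hg, , drop = FALSE], box = frames@box[k, ])
      coordinated <- apply(d <= cutoff, 1L, any)   # per donor atom
      if (!any(coordinated)) next
      counts <- tapply(as.integer(coordinated), res_key, sum)
      totals[names(counts), sp] <- totals[names(counts), sp] +
        unname(counts) * dur[w]
    }
  }
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- data.frame(subunit_id = parts[, 1],
                    residue_id = as.integer(parts[, 2]),
                    residue_name = parts[, 3], stringsAsFactors = FALSE,
                    row.names = NULL)
  for (sp in species) out[[paste0("ratio_", sp)]] <- totals[, sp] /
    total_time
  out[order(out$subunit_id, out$residue_id), , drop = FALSE]
}
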