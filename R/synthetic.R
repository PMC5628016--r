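# Ground-truth-labelled synthetic systems: an asymmetric bilayer around a
# two-subunit pseudo-protein whose four "lining helices" per subunit define
# the aqueduct cylinder, with scriptable lipid flip-flop events, ion
# crossings, per-slab aqueduct water and a toggling TM4-TM6 gate.  Every
# scripted event is logged so detectors can be validated against exact
# ground truth.

#' Script one lipid translocation event
#'
#' @param type `full_flop` (inner to outer), `full_flip` (outer to inner),
#'   `half_flop` (inner to midplane, unresolved at trajectory end) or
#'   `half_flip` (outer to midplane).
#' @param species `"POPC"` or `"POPS"`.
#' @param start,end event window in frames (1-based, inclusive).
#' @param subunit which aqueduct the lipid uses (`"I"` or `"II"`).
#' @param dwell fraction of the window spent at the central dwell site
#'   (z = -3 Angstrom, the mid-membrane interaction site).
#' @export
flipScript <- function(type, species = "POPC", start, end, subunit = "I",
                       dwell = 0.2) {
  type <- match.arg(type, c("full_flop", "full_flip", "half_flop",
                            "half_flip"))
  stopifnot(end > start, start >= 1, dwell >= 0, dwell < 0.8)
  list(kind = "flip", type = type, species = species,
       start = as.integer(start), end = as.integer(end),
       subunit = subunit, dwell = dwell)
}

#' Script one ion crossing through an aqueduct
#'
#' @param species `"Na"` or `"Cl"`.
#' @param direction `inward` (extracellular, z > 0, to intracellular) or
#'   `outward`.
#' @param start,end crossing window in frames.
#' @param subunit which aqueduct is used.
#' @export
ionScript <- function(species = "Na", direction = "inward", start, end,
                      subunit = "I") {
  direction <- match.arg(direction, c("inward", "outward"))
  stopifnot(end > start, start >= 1)
  list(kind = "ion", type = paste0("ion_", ifelse(direction == "inward",
                                                  "in", "out")),
       species = species, direction = direction, start = as.integer(start),
       end = as.integer(end), subunit = subunit)
}

#' The default event schedule
#'
#' The event mix reported for the combined 1700 ns trajectory, spread over
#' the available frames: five full floppings (3 POPC, 2 POPS, inner to
#' outer), three half-floppings (2 POPC, 1 POPS), one half-flipping (POPC),
#' and 24 inward Na+ crossings.
#'
#' @param n_frames frames available for scheduling.
#' @return list of [flipScript()]/[ionScript()] entries.
#' @export
defaultEventSchedule <- function(n_frames = 2000) {
  if (n_frames < 400)
    stop("the default schedule needs at least 400 frames")
  w <- floor(n_frames / 8)                  # one full event lasts ~n/8
  full <- list(c("POPC", "I"), c("POPC", "II"), c("POPC", "I"),
               c("POPS", "II"), c("POPS", "I"))
  sched <- vector("list", 0)
  for (i in seq_along(full)) {
    s <- 1 + (i - 1) * floor((n_frames - w - 10) / length(full))
    sched[[length(sched) + 1]] <-
      flipScript("full_flop", full[[i]][1], s, s + w, full[[i]][2])
  }
  half <- list(c("half_flop", "POPC", "I"), c("half_flop", "POPC", "II"),
               c("half_flop", "POPS", "I"), c("half_flip", "POPC", "II"))
  for (i in seq_along(half)) {
    s <- floor(n_frames * (0.55 + 0.08 * (i - 1)))
    sched[[length(sched) + 1]] <-
      flipScript(half[[i]][1], half[[i]][2], s, n_frames - 1, half[[i]][3])
  }
  wi <- max(20, floor(n_frames / 60))       # ion crossing duration
  for (i in seq_len(24)) {
    s <- 1 + floor((i - 1) * (n_frames - wi - 2) / 24)
    sched[[length(sched) + 1]] <-
      ionScript("Na", "inward", s, s + wi,
                subunit = if (i %% 2) "I" else "II")
  }
  sched
}

#' Define a synthetic scramblase scenario
#'
#' Defaults describe the simulated system: a 204 x 162 x 130 Angstrom box,
#' leaflet phosphates near z = +/-18 Angstrom, a pure-POPC outer leaflet and
#' a 2:1 POPC:POPS inner leaflet, two subunits each with four lining
#' helices, aqueduct water, free Na+/Cl- and protein-bound Ca2+.  The seed
#' fully determines the output.
#'
#' @param n_lipids_per_leaflet lipids per leaflet (default 128).
#' @param leaflet_z unsigned leaflet phosphate z, Angstrom.
#' @param box box edges, Angstrom.
#' @param inner_pops_fraction POPS fraction of the inner leaflet (1/3 gives
#'   the 2:1 POPC:POPS mixture).
#' @param event_schedule list of [flipScript()]/[ionScript()] entries;
#'   `NULL` = the [defaultEventSchedule()]; `list()` = no events.
#' @param water_per_slab aqueduct waters per 2-Angstrom slab per subunit.
#' @param pinch_schedule gate schedule: a duty-cycle fraction in [0, 1] or
#'   a logical vector per frame (TRUE = pinched).
#' @param n_na,n_cl free bulk ions.
#' @param noise_sigma i.i.d. Gaussian positional noise, Angstrom.
#' @param n_frames,dt frames and frame spacing (ns).
#' @param seed RNG seed.
#' @return a `SyntheticScenario` list.
#' @export
syntheticScenario <- function(n_lipids_per_leaflet = 128, leaflet_z = 18,
                              box = c(204, 162, 130),
                              inner_pops_fraction = 1 / 3,
                              event_schedule = NULL, water_per_slab = 15,
                              pinch_schedule = 0.063, n_na = 30, n_cl = 30,
                              noise_sigma = 0.5, n_frames = 2000, dt = 0.5,
                              seed = 1L) {
  if (is.null(event_schedule))
    event_schedule <- defaultEventSchedule(n_frames)
  if (is.numeric(pinch_schedule) && length(pinch_schedule) == 1L) {
    stopifnot(pinch_schedule >= 0, pinch_schedule <= 1)
    # evenly spread duty cycle: exactly floor(n * duty) pinched frames
    pinch_schedule <- diff(floor((0:n_frames) * pinch_schedule)) > 0
  }
  stopifnot(is.logical(pinch_schedule), length(pinch_schedule) == n_frames)
  for (ev in event_schedule)
    if (ev$end > n_frames)
      stop("scheduled event ends at frame ", ev$end,
           " but the scenario has only ", n_frames, " frames")
  structure(list(
    n_lipids_per_leaflet = n_lipids_per_leaflet, leaflet_z = leaflet_z,
    box = box, inner_pops_fraction = inner_pops_fraction,
    event_schedule = event_schedule, water_per_slab = water_per_slab,
    pinch_schedule = pinch_schedule, n_na = n_na, n_cl = n_cl,
    noise_sigma = noise_sigma, n_frames = as.integer(n_frames), dt = dt,
    seed = as.integer(seed),
    # fixed architecture of the pseudo-protein
    aqueduct_radius = 13, helix_radius = 8, subunit_offset = 30,
    gate_open = 8, gate_pinched = 2), class = "SyntheticScenario")
}

# residue ranges of the four lining helices of the pseudo-protein; the gate
# residues are 333 (TM4) and 439 (TM6)
#' Lining-helix residue ranges of the synthetic pseudo-protein
#' @return named list of integer ranges, one per lining helix.
#' @export
syntheticLiningRanges <- function() {
  list(TM3 = 281:294, TM4 = 325:338, TM5 = 355:368, TM6 = 433:446)
}

# linear interpolation through (frame, value) key points, constant outside
.keyPath <- function(kf, kv, n_frames) {
  stats::approx(kf, kv, xout = seq_len(n_frames), rule = 2)$y
}

# xy home positions on a grid, excluding a margin around both aqueduct axes
.homeGrid <- function(n, box, axes, margin, spacing = 9) {
  gx <- seq(spacing, box[1] - spacing, by = spacing)
  gy <- seq(spacing, box[2] - spacing, by = spacing)
  g <- as.matrix(expand.grid(x = gx, y = gy))
  keep <- rep(TRUE, nrow(g))
  for (i in seq_len(nrow(axes))) {
    d <- sqrt((g[, 1] - axes[i, 1])^2 + (g[, 2] - axes[i, 2])^2)
    keep <- keep & d > margin
  }
  g <- g[keep, , drop = FALSE]
  if (nrow(g) < n)
    stop("box too small: only ", nrow(g), " lipid/ion sites for ", n)
  g[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic system from a scenario
#'
#' Builds the atom table, the full coordinate trajectory and the ground
#' truth log.  Identical seeds give identical output.
#'
#' @param scenario a [syntheticScenario()].
#' @return list with `atoms`, `frames` ([FrameSet-class]) and `truth`
#'   (list: `events` data.frame, `pinch` logical vector, `n_frames`, `dt`).
#' @export
generateSystem <- function(scenario) {
  stopifnot(inherits(scenario, "SyntheticScenario"))
  sc <- scenario
  set.seed(sc$seed)
  nf <- sc$n_frames
  ctr <- c(sc$box[1] / 2, sc$box[2] / 2)
  axes <- rbind(I = c(ctr[1] - sc$subunit_offset, ctr[2]),
                II = c(ctr[1] + sc$subunit_offset, ctr[2]))

  ## ---- static architecture ------------------------------------------------
  an <- character(0); rn <- character(0); ri <- integer(0); su <- character(0)
  base <- NULL                      # n x 3 base coordinates
  addAtoms <- function(names, resname, resid, subunit, xyz) {
    an <<- c(an, names)
    rn <<- c(rn, rep(resname, length(names)))
    ri <<- c(ri, rep(as.integer(resid), length(names)))
    su <<- c(su, rep(subunit, length(names)))
    base <<- rbind(base, xyz)
  }

  ranges <- syntheticLiningRanges()
  helix_angles <- c(TM3 = 45, TM4 = 135, TM5 = 225, TM6 = 315) * pi / 180
  gate_info <- list()
  for (s in c("I", "II")) {
    ax <- axes[s, ]
    for (h in names(ranges)) {
      hx <- ax[1] + sc$helix_radius * cos(helix_angles[[h]])
      hy <- ax[2] + sc$helix_radius * sin(helix_angles[[h]])
      res <- ranges[[h]]
      zlev <- seq(-19.5, 19.5, length.out = length(res))
      for (j in seq_along(res)) {
        addAtoms(c("N", "CA", "O"), "ALA", res[j], s,
                 rbind(c(hx - 0.5, hy, zlev[j]),
                       c(hx, hy, zlev[j]),
                       c(hx + 0.5, hy, zlev[j] + 0.4)))
        # static sidechain stubs on the non-toggling gate-contact residues,
        # kept far from their partners so only the scripted 333/439 pair
        # can pinch
        if (res[j] %in% c(330L, 336L, 337L, 443L))
          addAtoms("CB", "LEU", res[j], s,
                   rbind(c(hx, hy + 0.8, zlev[j] + 0.5)))
      }
    }
    # gate sidechain atoms on the TM4/TM6 pair, midway between the helices
    p4 <- ax + sc$helix_radius * c(cos(helix_angles[["TM4"]]),
                                   sin(helix_angles[["TM4"]]))
    p6 <- ax + sc$helix_radius * c(cos(helix_angles[["TM6"]]),
                                   sin(helix_angles[["TM6"]]))
    mid <- (p4 + p6) / 2
    u <- (p6 - p4) / sqrt(sum((p6 - p4)^2))
    gz <- 0.5                              # gate sits near the midplane
    addAtoms("CG", "THR", 333L, s, rbind(c(mid - u * sc$gate_open / 2, gz)))
    i_cg <- nrow(base)
    addAtoms("OH", "TYR", 439L, s, rbind(c(mid + u * sc$gate_open / 2, gz)))
    gate_info[[s]] <- list(mid = mid, u = u, z = gz,
                           idx = c(i_cg, nrow(base)))
    # two bound Ca2+ at the regulatory site
    addAtoms("CAL", "CAL", 701L, s, rbind(c(ax[1], ax[2] + 3, -8)))
    addAtoms("CAL", "CAL", 702L, s, rbind(c(ax[1], ax[2] - 3, -8)))
  }

  ## ---- lipids -------------------------------------------------------------
  nlip <- sc$n_lipids_per_leaflet
  lip_xy <- .homeGrid(2 * nlip, sc$box, axes, sc$aqueduct_radius + 2)
  tail_names <- c(paste0("C2", 2:9), paste0("C3", 2:9))
  lipid_offsets <- function() {
    # offsets relative to P for an upper-leaflet lipid (tails point down)
    o <- rbind(P = c(0, 0, 0), N = c(0.8, 0, 1.0))
    t1 <- cbind(-0.6, 0, -2 - 1.5 * (0:7))
    t2 <- cbind(0.6, 0, -2 - 1.5 * (0:7))
    rbind(o, t1, t2)
  }
  off <- lipid_offsets()
  lip_meta <- data.frame(residue_id = integer(0), species = character(0),
                         leaflet = character(0), first_atom = integer(0))
  for (i in seq_len(2 * nlip)) {
    leaflet <- if (i <= nlip) "outer" else "inner"
    species <- if (leaflet == "outer") "POPC" else
      if ((i - nlip) %% 3 == 0) "POPS" else "POPC"
    sgn <- if (leaflet == "outer") 1 else -1
    p <- c(lip_xy[i, ], sgn * sc$leaflet_z)
    xyz <- cbind(p[1] + off[, 1], p[2] + off[, 2], p[3] + sgn * off[, 3])
    first <- length(an) + 1L
    addAtoms(c("P", "N1", tail_names), species, i, "MEMB", xyz)
    lip_meta <- rbind(lip_meta, data.frame(
      residue_id = i, species = species, leaflet = leaflet,
      first_atom = first, stringsAsFactors = FALSE))
  }
  n_lip_atoms <- nrow(off)

  ## ---- aqueduct water -----------------------------------------------------
  slab_lo <- seq(-20, 18, by = 2)
  wat_id <- 0L
  for (s in c("I", "II")) {
    ax <- axes[s, ]
    for (z0 in slab_lo) {
      for (j in seq_len(sc$water_per_slab)) {
        wat_id <- wat_id + 1L
        r <- (sc$aqueduct_radius - 1.5) * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        addAtoms("OH2", "TIP3", wat_id, "WAT",
                 rbind(c(ax[1] + r * cos(th), ax[2] + r * sin(th),
                         stats::runif(1, z0 + 0.2, z0 + 1.8))))
      }
    }
  }

  ## ---- ions ---------------------------------------------------------------
  n_ion <- sc$n_na + sc$n_cl
  ion_xy <- .homeGrid(2 * n_ion, sc$box, axes, sc$aqueduct_radius + 5,
                      spacing = 7)
  ion_meta <- data.frame(residue_id = integer(0), species = character(0),
                         atom = integer(0))
  for (i in seq_len(n_ion)) {
    species <- if (i <= sc$n_na) "Na" else "Cl"
    zside <- if (i %% 2) 32 else -32
    addAtoms(if (species == "Na") "SOD" else "CLA",
             if (species == "Na") "SOD" else "CLA", i, "ION",
             rbind(c(ion_xy[i, ], zside)))
    ion_meta <- rbind(ion_meta, data.frame(
      residue_id = i, species = species, atom = length(an),
      stringsAsFactors = FALSE))
  }

  n <- length(an)
  coords <- array(base, c(n, 3, nf))

  ## ---- scripted events ----------------------------------------------------
  truth <- data.frame(type = character(0), entity_id = integer(0),
                      species = character(0), subunit = character(0),
                      start_frame = integer(0), end_frame = integer(0),
                      direction = character(0), stringsAsFactors = FALSE)
  used_lipids <- integer(0); used_ions <- integer(0)
  for (ev in sc$event_schedule) {
    if (ev$kind == "flip") {
      from <- if (ev$type %in% c("full_flop", "half_flop")) "inner" else
        "outer"
      cand <- lip_meta[lip_meta$leaflet == from &
                         lip_meta$species == ev$species &
                         !(lip_meta$residue_id %in% used_lipids), ]
      if (!nrow(cand))
        stop("no free ", ev$species, " lipid left in the ", from,
             " leaflet for a ", ev$type, " event")
      lp <- cand[1, ]
      used_lipids <- c(used_lipids, lp$residue_id)
      ai <- lp$first_atom + seq_len(n_lip_atoms) - 1L
      ax <- axes[ev$subunit, ]
      sgn <- if (from == "inner") -1 else 1
      zL <- sc$leaflet_z
      home <- c(lip_xy[lp$residue_id, ], sgn * zL)
      w <- ev$end - ev$start
      edge <- sc$aqueduct_radius - 3
      if (ev$type %in% c("full_flop", "full_flip")) {
        kf <- ev$start + round(w * c(0, .1, .2, .4, .4 + ev$dwell,
                                     .7, .8, .9, 1))
        kx <- c(home[1], ax[1] + edge, ax[1], ax[1], ax[1], ax[1], ax[1],
                ax[1] + edge, home[1])
        ky <- c(home[2], ax[2], ax[2], ax[2], ax[2], ax[2], ax[2], ax[2],
                home[2])
        kz <- c(sgn * zL, sgn * zL, sgn * (zL - 2), -3, -3, -sgn * (zL - 4),
                -sgn * (zL - 2), -sgn * zL, -sgn * zL)
        ko <- c(sgn, sgn, sgn, 0.2 * sgn, 0.2 * sgn, -sgn, -sgn, -sgn,
                -sgn)
      } else {
        kf <- ev$start + round(w * c(0, .15, .3, .5, 1))
        kx <- c(home[1], ax[1] + edge, ax[1], ax[1], ax[1])
        ky <- c(home[2], ax[2], ax[2], ax[2], ax[2])
        kz <- c(sgn * zL, sgn * zL, sgn * (zL - 4), -3, -3)
        ko <- c(sgn, sgn, sgn, 0.3 * sgn, 0.3 * sgn)
      }
      dup <- duplicated(kf)
      kf <- pmin(kf[!dup], nf); kx <- kx[!dup]; ky <- ky[!dup]
      kz <- kz[!dup]; ko <- ko[!dup]
      px <- .keyPath(kf, kx, nf); py <- .keyPath(kf, ky, nf)
      pz <- .keyPath(kf, kz, nf); po <- .keyPath(kf, ko, nf)
      coords[ai, 1, ] <- outer(off[, 1], px, "+")
      coords[ai, 2, ] <- outer(off[, 2], py, "+")
      coords[ai, 3, ] <- off[, 3] %o% po +
        matrix(pz, n_lip_atoms, nf, byrow = TRUE)
      truth <- rbind(truth, data.frame(
        type = ev$type, entity_id = lp$residue_id, species = ev$species,
        subunit = ev$subunit, start_frame = ev$start, end_frame = ev$end,
        direction = if (from == "inner") "inner_to_outer" else
          "outer_to_inner", stringsAsFactors = FALSE))
    } else {                               # ion crossing
      pool <- ion_meta[ion_meta$species == ev$species &
                         !(ion_meta$residue_id %in% used_ions), ]
      if (!nrow(pool))
        stop("not enough free ", ev$species, " ions for the schedule")
      im <- pool[1, ]
      used_ions <- c(used_ions, im$residue_id)
      ai <- im$atom
      ax <- axes[ev$subunit, ]
      sgn <- if (ev$direction == "inward") 1 else -1
      home <- base[ai, ]
      w <- ev$end - ev$start
      kf <- ev$start + round(w * c(0, .15, .25, .75, .85, 1))
      kx <- c(home[1], ax[1], ax[1], ax[1], ax[1], ax[1])
      ky <- c(home[2], ax[2], ax[2], ax[2], ax[2], ax[2])
      kz <- sgn * c(32, 22, 16, -16, -22, -30)
      dup <- duplicated(kf)
      kf <- pmin(kf[!dup], nf); kx <- kx[!dup]; ky <- ky[!dup]
      kz <- kz[!dup]
      px <- .keyPath(kf, kx, nf); py <- .keyPath(kf, ky, nf)
      pz <- .keyPath(kf, kz, nf)
      coords[ai, 1, ] <- px; coords[ai, 2, ] <- py; coords[ai, 3, ] <- pz
      truth <- rbind(truth, data.frame(
        type = ev$type, entity_id = im$residue_id, species = ev$species,
        subunit = ev$subunit, start_frame = ev$start, end_frame = ev$end,
        direction = ev$direction, stringsAsFactors = FALSE))
    }
  }

  ## ---- gate toggling ------------------------------------------------------
  for (s in c("I", "II")) {
    g <- gate_info[[s]]
    sep <- ifelse(sc$pinch_schedule, sc$gate_pinched, sc$gate_open)
    coords[g$idx[1], 1, ] <- g$mid[1] - g$u[1] * sep / 2
    coords[g$idx[1], 2, ] <- g$mid[2] - g$u[2] * sep / 2
    coords[g$idx[2], 1, ] <- g$mid[1] + g$u[1] * sep / 2
    coords[g$idx[2], 2, ] <- g$mid[2] + g$u[2] * sep / 2
  }

  ## ---- noise and assembly -------------------------------------------------
  if (sc$noise_sigma > 0)
    coords <- coords + array(stats::rnorm(length(coords), 0,
                                          sc$noise_sigma), dim(coords))
  role <- classifyAtoms(an, rn, ri, su)
  role[rn == "CAL"] <- "bound_cation"
  atoms <- atomTable(an, rn, ri, su, role)
  frames <- FrameSet(coords, box = sc$box,
                     time = (seq_len(nf) - 1) * sc$dt)
  list(atoms = atoms, frames = frames,
       truth = list(events = truth, pinch = sc$pinch_schedule,
                    n_frames = nf, dt = sc$dt, seed = sc$seed))
}

#' Write a synthetic system as PDB + DCD + ground-truth JSON
#'
#' @param system output of [generateSystem()].
#' @param out_dir writable directory (created if missing).
#' @param format trajectory format: `"dcd"` or multi-model `"pdb"`.
#' @return named vector of written paths.
#' @export
writeFixture <- function(system, out_dir, format = c("dcd", "pdb")) {
  format <- match.arg(format)
  if (is.null(system$atoms) || !nrow(system$atoms))
    stop("cannot write an empty system")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  top <- file.path(out_dir, "system.pdb")
  writePDB(system$atoms, FrameSet(frameCoords(system$frames, 1L),
                                  boxDims(system$frames)[1, ],
                                  frameTimes(system$frames)[1]), top)
  if (format == "dcd") {
    trj <- file.path(out_dir, "trajectory.dcd")
    writeDCD(system$frames, trj)
  } else {
    trj <- file.path(out_dir, "trajectory.pdb")
    writePDB(system$atoms, system$frames, trj)
  }
  tru <- file.path(out_dir, "truth.json")
  jsonlite::write_json(system$truth, tru, auto_unbox = TRUE, digits = NA)
  c(topology = top, trajectory = trj, truth = tru)
}
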