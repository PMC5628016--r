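# Aqueduct cylinder definition, hydration, phosphate series, lipid traces,
# flip-flop detection and orientation angles.

test_that("defineAqueduct puts the axis at the lining-helix centroid and
           respects the dimer symmetry", {
  sys <- generateSystem(smallScenario(seed = 12, n_frames = 5,
                                      noise_sigma = 0,
                                      event_schedule = list()))
  cyls <- defineAqueduct(sys$atoms, sys$frames, syntheticLiningRanges())
  expect_named(cyls, c("I", "II"))
  expect_equal(cyls[["I"]]@radius, 13)
  expect_equal(cyls[["I"]]@slabThickness, 2)
  # oracle: the subunits are related by a 60 A translation along x, so
  # applying that symmetry operation to one axis gives the other
  expect_equal(cyls[["II"]]@axisXY[1] - cyls[["I"]]@axisXY[1], 60,
               tolerance = 1e-9)
  expect_equal(cyls[["I"]]@axisXY[2], cyls[["II"]]@axisXY[2],
               tolerance = 1e-9)
  # direct mean: two atoms at x 0 and 2 -> axis x = 1
  at <- tinyLipidSystem(c(50, 50, 18), protein_xyz = rbind(
    c(0, 0, 0), c(2, 0, 0)))
  cy <- defineAqueduct(at$atoms, at$frames, list(h = 1:2))
  expect_equal(unname(cy[[1]]@axisXY), c(1, 0))
  expect_error(defineAqueduct(at$atoms, at$frames, list(h = 900:905)),
               "900")
})

test_that("hydrationProfile matches the analytic uniform-density limit and
           the half-open slab rule", {
  # uniform water gas in a tall box around the cylinder
  set.seed(71); nw <- 4000
  box <- c(60, 60, 44)
  xyz <- cbind(runif(nw, 0, 60), runif(nw, 0, 60), runif(nw, -22, 22))
  at <- atomTable(c("CA", rep("OH2", nw)), c("ALA", rep("TIP3", nw)),
                  c(1L, seq_len(nw)), c("I", rep("WAT", nw)),
                  c("protein", rep("water", nw)))
  fs <- FrameSet(rbind(c(30, 30, 0), xyz), box)
  cyl <- defineAqueduct(at, fs, list(h = 1L), radius = 13,
                        z_extent = c(-20, 20))[[1]]
  prof <- hydrationProfile(at, fs, cyl)
  rho <- nw / prod(c(60, 60, 44))
  expected <- rho * pi * 13^2 * 2
  se <- sqrt(expected)                   # Poisson error per slab
  expect_true(all(abs(prof$mean_count - expected) < 3 * se))

  # boundary water assigned to the upper slab: z exactly 0 goes to [0, 2)
  at1 <- atomTable(c("CA", "OH2"), c("ALA", "TIP3"), c(1L, 1L),
                   c("I", "WAT"), c("protein", "water"))
  fs1 <- FrameSet(rbind(c(30, 30, 0), c(30, 30, 0)), box)
  cyl1 <- defineAqueduct(at1, fs1, list(h = 1L), z_extent = c(-20, 20))[[1]]
  prof1 <- hydrationProfile(at1, fs1, cyl1)
  expect_equal(prof1$mean_count[prof1$z_lower == 0], 1)
  expect_equal(prof1$mean_count[prof1$z_lower == -2], 0)
  expect_equal(sum(prof1$mean_count), 1)

  expect_error(hydrationProfile(at1, fs1, cyl1, window = 5:6), "window")
  # no water at all -> all-zero profile
  at2 <- at1; at2$role[2] <- "ion"; at2$residue_name[2] <- "SOD"
  expect_true(all(hydrationProfile(at2, fs1, cyl1)$mean_count == 0))
})

test_that("aqueductPhosphateSeries counts, averages and histograms the
           core occupancy", {
  # alternate 2 and 4 P atoms inside the core across frames
  nf <- 40
  xyz <- array(0, c(5, 3, nf))
  xyz[1, , ] <- c(30, 30, 0)                 # lining atom
  for (k in seq_len(nf)) {
    xyz[2, , k] <- c(30, 30, -3)             # always inside
    xyz[3, , k] <- c(32, 30, 3)              # always inside
    inz <- if (k %% 2) 5 else 50             # inside on odd frames
    xyz[4, , k] <- c(30, 32, inz)
    xyz[5, , k] <- c(28, 30, -inz)
  }
  at <- atomTable(c("CA", rep("P", 4)), c("ALA", rep("POPC", 4)),
                  c(1L, 1:4), c("I", rep("MEMB", 4)),
                  c("protein", rep("lipid_head", 4)))
  fs <- FrameSet(xyz, c(100, 100, 100))
  cyl <- defineAqueduct(at, fs, list(h = 1L))[[1]]
  res <- aqueductPhosphateSeries(at, fs, cyl)
  expect_equal(sort(unique(res$count)), c(2L, 4L))
  expect_equal(mean(res$count), 3.0)
  expect_equal(res$histogram$probability[res$histogram$count == 2], 0.5)
  expect_equal(res$histogram$probability[res$histogram$count == 4], 0.5)
  expect_equal(sum(res$histogram$probability), 1)
  # moving average of a constant series is that constant
  xyz0 <- xyz; xyz0[4, 3, ] <- 50; xyz0[5, 3, ] <- 50
  res0 <- aqueductPhosphateSeries(at, FrameSet(xyz0, c(100, 100, 100)), cyl)
  expect_true(all(res0$moving_average == 2))
})

test_that("traceLipids emits traces only for cylinder visitors and its
           histogram is conservative with the mode at the dwell site", {
  sys <- generateSystem(smallScenario(
    seed = 13, n_frames = 200, noise_sigma = 0,
    event_schedule = list(flipScript("half_flop", "POPC", 20, 199,
                                     dwell = 0.3))))
  cyl <- defineAqueduct(sys$atoms, sys$frames, syntheticLiningRanges())[["I"]]
  tl <- traceLipids(sys$atoms, sys$frames, cyl)
  expect_equal(length(tl$traces), 1L)       # only the scripted lipid
  expect_equal(attr(tl$traces[[1]], "species"), "POPC")
  # histogram total = total inside-cylinder samples
  expect_equal(sum(tl$histogram$count),
               sum(vapply(tl$traces, function(tr) sum(tr$inside), 0L)))
  # the half-flopped lipid parks at z = -3: modal bin is [-3, -2)
  mode_bin <- tl$histogram$z_lower[which.max(tl$histogram$count)]
  expect_equal(mode_bin, -3)
})

test_that("detectFlipEvents classifies full/half flips and flops with
           hysteresis", {
  # monotone crossing inner -> outer: one full_flop
  tr <- makeTrace(seq(-18, 18, length.out = 37))
  ev <- detectFlipEvents(list(tr))
  expect_equal(ev$class, "full_flop")
  # entry/exit times: leaves the -15 zone, completes on reaching +15
  expect_equal(ev$t_enter, 4)
  expect_equal(ev$t_exit, 33)

  # path to -1 that ends there: one half_flop
  ev2 <- detectFlipEvents(list(makeTrace(c(-18, -16, -10, -4, -1, -1))))
  expect_equal(ev2$class, "half_flop")

  # outer-leaflet start gives flips instead
  ev3 <- detectFlipEvents(list(makeTrace(seq(18, -18, length.out = 37))))
  expect_equal(ev3$class, "full_flip")
  ev4 <- detectFlipEvents(list(makeTrace(c(18, 16, 8, 3, 3))))
  expect_equal(ev4$class, "half_flip")

  # recrossing below the far zone then returning: no event
  bounce <- c(-18, -10, -3, 5, 10, 3, -5, -12, -18)
  expect_equal(nrow(detectFlipEvents(list(makeTrace(bounce)))), 0L)

  # a transit that never visits the cylinder interior is not attributed
  tr_out <- makeTrace(seq(-18, 18, length.out = 37), inside = FALSE)
  expect_equal(nrow(detectFlipEvents(list(tr_out))), 0L)

  # sequential events from one lipid are all reported
  zz <- c(seq(-18, 18, length.out = 19), seq(18, -18, length.out = 19))
  evs <- detectFlipEvents(list(makeTrace(zz)))
  expect_equal(evs$class, c("full_flop", "full_flip"))
})

test_that("a full event flips the lipid leaflet label", {
  sys <- generateSystem(smallScenario(
    seed = 14, n_frames = 200, noise_sigma = 0.5,
    event_schedule = list(flipScript("full_flop", "POPS", 10, 150))))
  before <- assignLeaflets(sys$atoms, sys$frames, frame = 1L)
  after <- assignLeaflets(sys$atoms, sys$frames, frame = 200L)
  cyl <- defineAqueduct(sys$atoms, sys$frames,
                        syntheticLiningRanges())[["I"]]
  ev <- detectFlipEvents(traceLipids(sys$atoms, sys$frames, cyl)$traces)
  expect_equal(nrow(ev), 1L)
  lid <- ev$lipid_id
  expect_equal(before$leaflet[before$residue_id == lid], "inner")
  expect_equal(after$leaflet[after$residue_id == lid], "outer")
})

test_that("tail tilt and P-N dipole angles reproduce the constructed
           geometries and are invariant to rotation about z", {
  tail_names <- c(paste0("C2", 2:9), paste0("C3", 2:9))
  mkLipid <- function(t1_dir, t2_dir, n_dir = c(0, 0, 1)) {
    an <- c("P", "N1", tail_names)
    xyz <- matrix(0, 18, 3)
    xyz[2, ] <- n_dir
    for (j in 1:8) xyz[2 + j, ] <- j * t1_dir
    for (j in 1:8) xyz[10 + j, ] <- j * t2_dir
    at <- atomTable(an, rep("POPC", 18), rep(1L, 18), rep("MEMB", 18),
                    c("lipid_head", "lipid_head", rep("lipid_tail", 16)))
    list(atoms = at, frames = FrameSet(xyz + 50, c(200, 200, 200)))
  }
  # both tails along -z -> 180; symmetric about +z -> 0; +z & +x -> 45
  s1 <- mkLipid(c(0, 0, -1), c(0, 0, -1))
  expect_equal(tailTiltAngles(s1$atoms, s1$frames, 1), 180)
  s2 <- mkLipid(c(0.3, 0, 1), c(-0.3, 0, 1))
  expect_equal(tailTiltAngles(s2$atoms, s2$frames, 1), 0)
  s3 <- mkLipid(c(0, 0, 1), c(1, 0, 0))
  expect_equal(tailTiltAngles(s3$atoms, s3$frames, 1), 45)
  # antiparallel tails: degenerate, flagged NA
  s4 <- mkLipid(c(0, 0, 1), c(0, 0, -1))
  expect_true(is.na(tailTiltAngles(s4$atoms, s4$frames, 1)))

  # P-N dipole: N above P -> 0; below -> 180; 45 degree elevation -> 45
  expect_equal(pnDipoleAngles(s1$atoms, s1$frames, 1)$angle, 0)
  s5 <- mkLipid(c(0, 0, -1), c(0, 0, -1), n_dir = c(0, 0, -1))
  expect_equal(pnDipoleAngles(s5$atoms, s5$frames, 1)$angle, 180)
  s6 <- mkLipid(c(0, 0, -1), c(0, 0, -1), n_dir = c(1, 0, 1))
  expect_equal(pnDipoleAngles(s6$atoms, s6$frames, 1)$angle, 45)

  # invariance under rotation about z (and xy-translation)
  th <- 0.9
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  s7 <- mkLipid(c(0.4, 0.2, 1), c(-0.1, 0.3, 0.9), n_dir = c(0.5, 0.1, 1))
  rot <- s7$frames
  rot@coords[, , 1] <- sweep(rot@coords[, , 1], 2, c(50, 50, 50)) %*%
    t(R) + matrix(c(60, 40, 50), 18, 3, byrow = TRUE)
  expect_equal(tailTiltAngles(s7$atoms, rot, 1),
               tailTiltAngles(s7$atoms, s7$frames, 1), tolerance = 1e-9)
  expect_equal(pnDipoleAngles(s7$atoms, rot, 1)$angle,
               pnDipoleAngles(s7$atoms, s7$frames, 1)$angle,
               tolerance = 1e-9)
})
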