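# Contact and coordination statistics against O(N^2) brute-force oracles.

# a random mixed system: protein backbone N/CA/O atoms plus head-group
# P/O/N lipids, all in one frame
randomContactSystem <- function(seed, n_res = 30, n_lip = 25,
                                box = c(60, 60, 60)) {
  set.seed(seed)
  an <- c(); rn <- c(); ri <- c(); su <- c(); ro <- c()
  for (i in seq_len(n_res)) {
    an <- c(an, "N", "CA", "O"); rn <- c(rn, rep("ALA", 3))
    ri <- c(ri, rep(i, 3)); su <- c(su, rep("I", 3))
    ro <- c(ro, rep("protein", 3))
  }
  for (i in seq_len(n_lip)) {
    an <- c(an, "P", "N1", "C22", "C23")
    rn <- c(rn, rep("POPC", 4)); ri <- c(ri, rep(i, 4))
    su <- c(su, rep("MEMB", 4))
    ro <- c(ro, "lipid_head", "lipid_head", "lipid_tail", "lipid_tail")
  }
  n <- length(an)
  xyz <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]),
               runif(n, 0, box[3]))
  list(atoms = atomTable(an, rn, ri, su, ro),
       frames = FrameSet(xyz, box))
}

test_that("polarContacts applies the 4 A threshold, the cylinder
           restriction, and matches brute force", {
  # constructed pair at 3.9 A contacts; at 4.1 A does not
  at <- atomTable(c("O", "P", "N1"), c("ALA", "POPC", "POPC"),
                  c(1L, 1L, 1L), c("I", "MEMB", "MEMB"),
                  c("protein", "lipid_head", "lipid_head"))
  xyz <- rbind(c(10, 10, 0), c(10, 13.9, 0), c(10, 14.1, 0))
  fs <- FrameSet(xyz, c(50, 50, 50))
  pc <- polarContacts(at, fs)
  expect_equal(nrow(pc), 1L)
  expect_equal(pc$distance, 3.9)

  # brute-force equivalence on a random 220-atom frame
  sys <- randomContactSystem(81)
  got <- polarContacts(sys$atoms, sys$frames)
  prot <- which(sys$atoms$role == "protein" &
                  sys$atoms$element %in% c("N", "O"))
  head <- which(sys$atoms$role == "lipid_head" &
                  sys$atoms$element %in% c("N", "O", "P"))
  brute <- bruteContacts(frameCoords(sys$frames, 1), prot, head, 4,
                         c(60, 60, 60))
  key <- function(a, b) paste(a, b, sep = "-")
  expect_setequal(key(got$protein_atom, got$lipid_atom),
                  key(brute[, 1], brute[, 2]))

  # a head group outside the cylinder is excluded regardless of distance
  lining <- atomTable(c("CA", "O", "P"), c("ALA", "ALA", "POPC"),
                      c(1L, 2L, 1L), c("I", "I", "MEMB"),
                      c("protein", "protein", "lipid_head"))
  # lipid P is 2 A from the protein O but 30 A from the cylinder axis
  xyzc <- rbind(c(10, 10, 0), c(40, 10, 0), c(40, 12, 0))
  fsc <- FrameSet(xyzc, c(100, 100, 100))
  cyl <- defineAqueduct(lining, fsc, list(h = 1L))[[1]]   # axis at (10, 10)
  expect_equal(nrow(polarContacts(lining, fsc, cylinder = cyl)), 0L)
  expect_gt(nrow(polarContacts(lining, fsc, cylinder = NULL)), 0L)
})

test_that("hydrophobicContacts is carbon-carbon only and matches brute
           force", {
  at <- atomTable(c("CA", "O", "C22", "P"), c("ALA", "ALA", "POPC", "POPC"),
                  c(1L, 1L, 1L, 1L), c("I", "I", "MEMB", "MEMB"),
                  c("protein", "protein", "lipid_tail", "lipid_head"))
  xyz <- rbind(c(10, 10, 0), c(10, 12, 0), c(10, 13.5, 0), c(40, 40, 0))
  fs <- FrameSet(xyz, c(50, 50, 50))
  hc <- hydrophobicContacts(at, fs)
  expect_equal(nrow(hc), 1L)          # CA-C22 at 3.5; O-C22 pair excluded
  expect_equal(hc$distance, 3.5)

  sys <- randomContactSystem(82)
  got <- hydrophobicContacts(sys$atoms, sys$frames)
  protC <- which(sys$atoms$role == "protein" & sys$atoms$element == "C")
  tailC <- which(sys$atoms$role == "lipid_tail" & sys$atoms$element == "C")
  brute <- bruteContacts(frameCoords(sys$frames, 1), protC, tailC, 4,
                         c(60, 60, 60))
  expect_equal(nrow(got), if (is.null(brute)) 0L else nrow(brute))
})

test_that("residueContactFraction counts >= 1 contact per frame and is
           duration-additive", {
  # residue 1 in contact 3 of 10 frames -> 0.3
  nf <- 10
  xyz <- array(0, c(2, 3, nf))
  xyz[1, , ] <- c(10, 10, 0)
  for (k in seq_len(nf))
    xyz[2, , k] <- c(10, if (k <= 3) 13 else 30, 0)
  at <- atomTable(c("O", "P"), c("ALA", "POPC"), c(1L, 1L),
                  c("I", "MEMB"), c("protein", "lipid_head"))
  fs <- FrameSet(xyz, c(60, 60, 60))
  cf <- residueContactFraction(at, fs,
                               function(k) polarContacts(at, fs, k))
  expect_equal(cf$fraction, 0.3)

  # scripted 36.8% duty cycle over 250 frames
  nf2 <- 250; duty <- round(0.368 * nf2)
  xyz2 <- array(0, c(2, 3, nf2))
  xyz2[1, , ] <- c(10, 10, 0)
  for (k in seq_len(nf2))
    xyz2[2, , k] <- c(10, if (k <= duty) 12 else 40, 0)
  fs2 <- FrameSet(xyz2, c(60, 60, 60))
  cf2 <- residueContactFraction(at, fs2,
                                function(k) polarContacts(at, fs2, k))
  expect_equal(cf2$fraction, 0.368, tolerance = 1 / nf2)

  # additivity: full-window fraction = weighted mean over sub-windows
  w1 <- 1:100; w2 <- 101:250
  f1 <- residueContactFraction(at, fs2,
                               function(k) polarContacts(at, fs2, k), w1)
  f2 <- residueContactFraction(at, fs2,
                               function(k) polarContacts(at, fs2, k), w2)
  f2v <- if (nrow(f2)) f2$fraction else 0
  expect_equal(cf2$fraction,
               (f1$fraction * 100 + f2v * 150) / 250)
})

test_that("coordinationSeries matches constructions and brute force", {
  # octahedral cage of 6 water O at 2.4 A around a Na ion
  cage <- rbind(c(2.4, 0, 0), c(-2.4, 0, 0), c(0, 2.4, 0),
                c(0, -2.4, 0), c(0, 0, 2.4), c(0, 0, -2.4))
  an <- c("SOD", rep("OH2", 6)); rn <- c("SOD", rep("TIP3", 6))
  at <- atomTable(an, rn, c(1L, 1:6), c("ION", rep("WAT", 6)),
                  c("ion", rep("water", 6)))
  fs <- FrameSet(rbind(c(0, 0, 0), cage) + 30, c(60, 60, 60))
  cs <- coordinationSeries(at, fs, list(kind = "ion", residue_id = 1L,
                                        subunit_id = "ION"))
  expect_equal(cs$water_O, 6L)
  expect_equal(cs$protein_O_N, 0L)

  # isolated ion: all zeros
  far <- FrameSet(rbind(c(0, 0, 0), cage + 20) + 15, c(60, 60, 60))
  cs0 <- coordinationSeries(at, far, list(kind = "ion", residue_id = 1L,
                                          subunit_id = "ION"))
  expect_true(all(cs0$water_O == 0))

  # brute-force equivalence on random frames, ion and lipid centres
  sys <- randomContactSystem(83)
  # add a Na ion and some waters into the same frame
  extra_an <- c("SOD", rep("OH2", 30))
  at2 <- atomTable(c(sys$atoms$atom_name, extra_an),
                   c(sys$atoms$residue_name, "SOD", rep("TIP3", 30)),
                   c(sys$atoms$residue_id, 1L, 1:30),
                   c(sys$atoms$subunit_id, "ION", rep("WAT", 30)),
                   c(sys$atoms$role, "ion", rep("water", 30)))
  set.seed(84)
  xyz2 <- rbind(frameCoords(sys$frames, 1),
                cbind(runif(31, 0, 60), runif(31, 0, 60),
                      runif(31, 0, 60)))
  fs2 <- FrameSet(xyz2, c(60, 60, 60))
  ion_i <- which(at2$role == "ion")
  cs2 <- coordinationSeries(at2, fs2, list(kind = "ion", residue_id = 1L,
                                           subunit_id = "ION"))
  for (cls in list(c("water_O", "water", "O"),
                   c("protein_O_N", "protein", "N|O"),
                   c("lipid_O_N", "lipid", "N|O"))) {
    donors <- which(grepl(cls[2], at2$role) &
                      grepl(cls[3], at2$element))
    expect_equal(cs2[[cls[1]]],
                 bruteCoordCount(xyz2, donors, ion_i, 3, c(60, 60, 60)))
  }

  # lipid-centred series: donors counted once per frame around the whole
  # head group, excluding the lipid itself
  csl <- coordinationSeries(at2, fs2,
                            list(kind = "lipid", residue_id = 1L,
                                 subunit_id = "MEMB"))
  own <- which(at2$residue_id == 1L & at2$subunit_id == "MEMB")
  ctr <- own[at2$element[own] %in% c("P", "O", "N") &
               at2$role[own] == "lipid_head"]
  lip_donors <- setdiff(which(at2$role %in% c("lipid_head", "lipid_tail") &
                                at2$element %in% c("N", "O")), own)
  expect_equal(csl$lipid_O_N,
               bruteCoordCount(xyz2, lip_donors, ctr, 3, c(60, 60, 60)))
})

test_that("event averages, histograms and coordination ratios follow their
           definitions", {
  mkSeries <- function(counts, dt = 1) {
    s <- data.frame(time = (seq_along(counts) - 1) * dt,
                    water_O = counts, protein_O_N = 0L, lipid_O_N = 0L)
    s
  }
  # constant count 6 -> mean 6; equal-duration 4 then 6 -> 5
  expect_equal(eventAverageCoordination(mkSeries(rep(6L, 10)))$mean, 6)
  expect_equal(eventAverageCoordination(mkSeries(rep(c(4L, 6L), 10)))$mean,
               5)
  s <- mkSeries(rep(2L, 8)); s$protein_O_N <- 1L; s$lipid_O_N <- 1L
  pct <- eventAverageCoordination(s)$percent
  expect_equal(sum(pct), 100)
  expect_error(eventAverageCoordination(mkSeries(1L), c(5, 5)), "zero")

  # histogram: all zeros -> mass at 0, fraction 0; half 2 half 0 -> 0.5
  h0 <- headgroupCoordinationHistogram(mkSeries(rep(0L, 10)),
                                       donor = "water_O")
  expect_equal(h0$histogram$probability, 1)
  expect_equal(h0$fraction_at_least, 0)
  h1 <- headgroupCoordinationHistogram(mkSeries(rep(c(2L, 0L), 10)),
                                       donor = "water_O")
  expect_equal(h1$fraction_at_least, 0.5)
  expect_equal(sum(h1$histogram$probability), 1)
})

test_that("coordinationRatio is a rate, additive over windows, and ranks a
           scripted POPS-binding residue above POPC", {
  # one protein O coordinating one POPS head group for 100 of 500 frames
  nf <- 500
  an <- c("O", "P", "P")
  at <- atomTable(an, c("ALA", "POPS", "POPC"), c(1L, 1L, 2L),
                  c("I", "MEMB", "MEMB"),
                  c("protein", "lipid_head", "lipid_head"))
  xyz <- array(0, c(3, 3, nf))
  xyz[1, , ] <- c(10, 10, 0)
  for (k in seq_len(nf)) {
    xyz[2, , k] <- c(10, if (k <= 100) 12 else 40, 0)   # POPS: 100 frames
    xyz[3, , k] <- c(10, if (k <= 20) 12 else 40, 0)    # POPC: 20 frames
  }
  fs <- FrameSet(xyz, c(60, 60, 60), time = (seq_len(nf) - 1) * 1)
  cr <- coordinationRatio(at, fs)
  # 100 coordination-frames x 1 ns / 500 ns = 0.2 /ns
  expect_equal(cr$ratio_POPS, 0.2)
  expect_equal(cr$ratio_POPC, 0.04)
  expect_gt(cr$ratio_POPS, cr$ratio_POPC)   # scripted selectivity ordering

  # rate property: a window concatenated with itself keeps the ratio
  half <- coordinationRatio(at, fs, window = 1:250)
  whole_rate <- coordinationRatio(at, fs, window = c(1:250, 1:250))
  expect_equal(whole_rate$ratio_POPS, half$ratio_POPS)
})
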