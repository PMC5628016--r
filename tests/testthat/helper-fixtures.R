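# Shared builders and independent brute-force oracles.  Oracles use plain
# double loops and never call the package's vectorised geometry helpers.

# minimal atom table: one "protein" pseudo-atom chain plus n free lipids
# whose only atoms are a P and an N
tinyLipidSystem <- function(p_xyz, protein_xyz = NULL, box = c(100, 100, 100),
                            species = rep("POPC", nrow(rbind(p_xyz)))) {
  p_xyz <- rbind(p_xyz)
  nlip <- nrow(p_xyz)
  an <- c(); rn <- c(); ri <- c(); su <- c(); ro <- c(); xyz <- NULL
  if (!is.null(protein_xyz)) {
    protein_xyz <- rbind(protein_xyz)
    np <- nrow(protein_xyz)
    an <- c(an, rep("CA", np)); rn <- c(rn, rep("ALA", np))
    ri <- c(ri, seq_len(np)); su <- c(su, rep("I", np))
    ro <- c(ro, rep("protein", np)); xyz <- rbind(xyz, protein_xyz)
  }
  for (i in seq_len(nlip)) {
    an <- c(an, "P", "N1"); rn <- c(rn, species[i], species[i])
    ri <- c(ri, i, i); su <- c(su, "MEMB", "MEMB")
    ro <- c(ro, "lipid_head", "lipid_head")
    xyz <- rbind(xyz, p_xyz[i, ], p_xyz[i, ] + c(0, 0, 1))
  }
  list(atoms = atomTable(an, rn, ri, su, ro),
       frames = FrameSet(xyz, box))
}

# brute-force minimum-image distance between two points
bruteDist <- function(a, b, box) {
  d <- a - b
  for (ax in 1:3) {
    while (d[ax] > box[ax] / 2) d[ax] <- d[ax] - box[ax]
    while (d[ax] < -box[ax] / 2) d[ax] <- d[ax] + box[ax]
  }
  sqrt(sum(d^2))
}

# brute-force contact pair list between two index sets at one frame
bruteContacts <- function(xyz, idx_a, idx_b, cutoff, box) {
  out <- NULL
  for (i in idx_a) for (j in idx_b)
    if (bruteDist(xyz[i, ], xyz[j, ], box) <= cutoff)
      out <- rbind(out, c(i, j))
  out
}

# brute-force count of donor atoms within cutoff of any centre atom
bruteCoordCount <- function(xyz, donor_idx, centre_idx, cutoff, box) {
  n <- 0L
  for (i in donor_idx) {
    hit <- FALSE
    for (j in centre_idx)
      if (bruteDist(xyz[i, ], xyz[j, ], box) <= cutoff) hit <- TRUE
    if (hit) n <- n + 1L
  }
  n
}

# a straight z-trace builder for event-detector tests
makeTrace <- function(z, inside = TRUE, lipid_id = 1L, species = "POPC",
                      subunit = "I", dt = 1) {
  tr <- data.frame(time = (seq_along(z) - 1) * dt, z = z,
                   inside = rep_len(inside, length(z)))
  attr(tr, "lipid_id") <- lipid_id
  attr(tr, "species") <- species
  attr(tr, "subunit") <- subunit
  tr
}

# small scenario used by several suites (fast: < 2 s to generate)
smallScenario <- function(..., n_frames = 300) {
  syntheticScenario(n_lipids_per_leaflet = 30, n_frames = n_frames,
                    water_per_slab = 4, n_na = 10, n_cl = 10, ...)
}
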