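# Lipid-protein contact statistics: 4-Angstrom electrostatic (polar) and
# hydrophobic (carbon-carbon) contacts and per-residue contact-time
# fractions.  Cutoffs are inclusive (<=) and configurable.

# polar (N/O, plus lipid P) atom masks
.proteinPolarIdx <- function(atoms)
  which(atoms$role == "protein" & atoms$element %in% c("N", "O"))
.headgroupPolarIdx <- function(atoms)
  which(atoms$role == "lipid_head" & atoms$element %in% c("N", "O", "P"))

# generic cutoff contact search at one frame; returns a pair table
.contactPairs <- function(frames, k, idx_a, idx_b, cutoff, box = NULL) {
  if (!length(idx_a) || !length(idx_b))
    return(data.frame(atom_a = integer(0), atom_b = integer(0),
                      distance = numeric(0)))
  xyz <- frameCoords(frames, k)
  d <- pairDistances(xyz[idx_a, , drop = FALSE],
                     xyz[idx_b, , drop = FALSE], box = box)
  hit <- which(d <= cutoff, arr.ind = TRUE)
  data.frame(atom_a = idx_a[hit[, 1]], atom_b = idx_b[hit[, 2]],
             distance = d[hit])
}

#' Electrostatic (polar) lipid-protein contacts at one frame
#'
#' All (protein N/O atom, lipid head-group N/O/P atom) pairs within the
#' cutoff, restricted to head groups whose atoms lie inside the aqueduct
#' cylinder (radially within the radius and z within the cylinder extent).
#'
#' @param atoms atom table.
#' @param frames [FrameSet-class].
#' @param k frame index.
#' @param cylinder an [AqueductCylinder-class] restricting the head
#'   groups, or `NULL` for no restriction.
#' @param cutoff contact cutoff, Angstrom (field convention 4).
#' @return data.frame of pairs: `protein_atom`, `lipid_atom`, `distance`,
#'   plus residue annotation of the protein atom.
#' @export
polarContacts <- function(atoms, frames, k = 1L, cylinder = NULL,
                          cutoff = 4) {
  prot <- .proteinPolarIdx(atoms)
  head <- .headgroupPolarIdx(atoms)
  if (!length(prot) || !length(head))
    stop("empty protein-polar or head-group selection")
  if (!is.null(cylinder)) {
    xyz <- frameCoords(frames, k)
    hxyz <- xyz[head, , drop = FALSE]
    r <- .radialDist(cylinder, frames, k, hxyz)
    inz <- hxyz[, 3] >= cylinder@zExtent[1] &
      hxyz[, 3] <= cylinder@zExtent[2]
    head <- head[r <= cylinder@radius & inz]
  }
  pr <- .contactPairs(frames, k, prot, head, cutoff,
                      box = frames@box[k, ])
  data.frame(protein_atom = pr$atom_a, lipid_atom = pr$atom_b,
             distance = pr$distance,
             residue_id = atoms$residue_id[pr$atom_a],
             residue_name = atoms$residue_name[pr$atom_a],
             subunit_id = atoms$subunit_id[pr$atom_a],
             stringsAsFactors = FALSE)
}

#' Hydrophobic (carbon-carbon) lipid-protein contacts at one frame
#'
#' All (protein carbon, lipid tail carbon) pairs within the cutoff; no
#' cylinder restriction.
#'
#' @inheritParams polarContacts
#' @return data.frame of pairs as in [polarContacts()].
#' @export
hydrophobicContacts <- function(atoms, frames, k = 1L, cutoff = 4) {
  prot <- which(atoms$role == "protein" & atoms$element == "C")
  tail <- which(atoms$role == "lipid_tail" & atoms$element == "C")
  if (!length(prot) || !length(tail))
    stop("empty protein-carbon or tail-carbon selection")
  pr <- .contactPairs(frames, k, prot, tail, cutoff,
                      box = frames@box[k, ])
  data.frame(protein_atom = pr$atom_a, lipid_atom = pr$atom_b,
             distance = pr$distance,
             residue_id = atoms$residue_id[pr$atom_a],
             residue_name = atoms$residue_name[pr$atom_a],
             subunit_id = atoms$subunit_id[pr$atom_a],
             stringsAsFactors = FALSE)
}

#' Fraction of frames each residue is in contact
#'
#' A residue counts as in contact in a frame if it forms at least one
#' contact pair that frame; the fraction divides by the number of frames
#' in the window.
#'
#' @param atoms atom table.
#' @param frames [FrameSet-class].
#' @param contact_fun per-frame contact function, e.g.
#'   `function(k) polarContacts(atoms, frames, k, cylinder)`.
#' @param window frame indices (default: all).
#' @return data.frame `subunit_id`, `residue_id`, `residue_name`,
#'   `fraction`, sorted by decreasing fraction.
#' @export
residueContactFraction <- function(atoms, frames, contact_fun,
                                   window = NULL) {
  if (is.null(window)) window <- seq_len(nFrames(frames))
  if (!length(window)) stop("empty analysis window")
  acc <- new.env(parent = emptyenv())
  for (k in window) {
    pr <- contact_fun(k)
    if (!nrow(pr)) next
    keys <- unique(paste(pr$subunit_id, pr$residue_id, pr$residue_name,
                         sep = "\r"))
    for (key in keys)
      assign(key, (if (exists(key, acc)) get(key, acc) else 0L) + 1L, acc)
  }
  keys <- ls(acc)
  if (!length(keys))
    return(data.frame(subunit_id = character(0), residue_id = integer(0),
                      residue_name = character(0), fraction = numeric(0),
                      stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- data.frame(subunit_id = parts[, 1],
                    residue_id = as.integer(parts[, 2]),
                    residue_name = parts[, 3],
                    fraction = vapply(keys, get, 0L, envir = acc) /
                      length(window),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$fraction, out$subunit_id, out$residue_id), ,
      drop = FALSE]
}
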