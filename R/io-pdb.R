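# Minimal fixed-width PDB reader/writer (no MD I/O package exists in this
# R stack).  Supports multi-model files, CRYST1 boxes and CHARMM-style
# segment identifiers (columns 73-76) used to carry subunit labels longer
# than the one-character chain id.

#' Read a (multi-model) PDB file
#'
#' Parses ATOM/HETATM records, MODEL/ENDMDL frames and the CRYST1 box.
#' Orthorhombic boxes only; a CRYST1 with non-90 angles is rejected.
#'
#' @param path PDB file.
#' @return list with `atom_name`, `residue_name`, `residue_id`,
#'   `subunit_id` (segment id, falling back to chain id), `coords`
#'   (`n_atoms x 3 x n_models` array, Angstrom) and `box` (length-3 or NA).
#' @export
readPDB <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  box <- rep(NA_real_, 3)
  cryst <- lines[startsWith(lines, "CRYST1")]
  if (length(cryst)) {
    v <- as.numeric(c(substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
                      substr(cryst[1], 25, 33), substr(cryst[1], 34, 40),
                      substr(cryst[1], 41, 47), substr(cryst[1], 48, 54)))
    if (any(abs(v[4:6] - 90) > 1e-3))
      stop("triclinic CRYST1 box (angles != 90) is not supported")
    box <- v[1:3]
  }
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (!length(model_starts)) model_starts <- 0L
  ends <- c(model_starts[-1], length(lines) + 1L)
  frames <- lapply(seq_along(model_starts), function(i) {
    idx <- which(is_atom & seq_along(lines) > model_starts[i] &
                   seq_along(lines) < ends[i])
    lines[idx]
  })
  frames <- frames[vapply(frames, length, 1L) > 0L]
  if (!length(frames)) stop("no ATOM records in ", path)
  n <- length(frames[[1]])
  if (any(vapply(frames, length, 1L) != n))
    stop("models differ in atom count in ", path)
  first <- frames[[1]]
  atom_name <- trimws(substr(first, 13, 16))
  residue_name <- trimws(substr(first, 18, 21))
  chain <- trimws(substr(first, 22, 22))
  residue_id <- as.integer(substr(first, 23, 26))
  segid <- trimws(substr(first, 73, 76))
  subunit <- ifelse(nzchar(segid), segid, chain)
  coords <- array(NA_real_, c(n, 3, length(frames)))
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    coords[, 1, k] <- as.numeric(substr(f, 31, 38))
    coords[, 2, k] <- as.numeric(substr(f, 39, 46))
    coords[, 3, k] <- as.numeric(substr(f, 47, 54))
  }
  list(atom_name = atom_name, residue_name = residue_name,
       residue_id = residue_id, subunit_id = subunit,
       coords = coords, box = box)
}

#' Write a (multi-model) PDB file
#'
#' @param atoms atom table (see [atomTable()]).
#' @param frames a [FrameSet-class]; all frames are written as MODELs.
#' @param path output file.
#' @export
writePDB <- function(atoms, frames, path) {
  stopifnot(nrow(atoms) == nAtoms(frames))
  con <- file(path, "w")
  on.exit(close(con))
  b <- boxDims(frames)[1, ]
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    b[1], b[2], b[3], 90, 90, 90), con)
  serial <- ((atoms$atom_id - 1L) %% 99999L) + 1L
  nm <- atoms$atom_name
  nm4 <- ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
  chain <- substr(atoms$subunit_id, 1, 1)
  seg <- substr(atoms$subunit_id, 1, 4)
  multi <- nFrames(frames) > 1L
  for (k in seq_len(nFrames(frames))) {
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    xyz <- frameCoords(frames, k)
    writeLines(sprintf(
      "ATOM  %5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00      %-4s%2s",
      serial, nm4, substr(atoms$residue_name, 1, 4), chain,
      atoms$residue_id %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3], seg,
      substr(atoms$element, 1, 2)), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
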