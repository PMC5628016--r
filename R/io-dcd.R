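# CHARMM/NAMD DCD binary trajectory reader/writer, implemented directly with
# readBin/writeBin (little-endian, 32-bit Fortran record markers; the layout
# NAMD and VMD write).  Unit cell records use the CHARMM XTLABC ordering
# [A, gamma, B, beta, alpha, C]; only orthorhombic cells are supported.

#' Write a FrameSet as a DCD trajectory
#'
#' DCD stores a single uniform time step; if frame times are not uniformly
#' spaced the mean spacing is stored with a warning.  Coordinates are
#' float32, so the roundtrip precision is ~1e-5 Angstrom at membrane box
#' scales.
#'
#' @param frames a [FrameSet-class].
#' @param path output file.
#' @export
writeDCD <- function(frames, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- nFrames(frames); na <- nAtoms(frames)
  tm <- frameTimes(frames)
  dt_ps <- if (nf > 1L) diff(tm) * 1000 else 1
  if (nf > 2L && diff(range(dt_ps)) > 1e-6 * mean(dt_ps))
    warning("DCD stores a uniform time step; using the mean frame spacing")
  delta <- mean(dt_ps)
  t0_steps <- as.integer(round(tm[1] * 1000 / delta))
  rec <- function(payload_writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
    payload_writer()
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nf          # number of frames
  icntrl[2] <- t0_steps    # step of first frame
  icntrl[3] <- 1L          # steps between frames
  icntrl[4] <- t0_steps + nf - 1L
  icntrl[10] <- .floatBits(delta)  # time step, stored as float32 bit pattern
  icntrl[11] <- 1L         # unit cell present
  icntrl[20] <- 24L        # CHARMM version flag
  rec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(as.integer(icntrl), con, size = 4, endian = "little")
  }, 84)
  title <- sprintf("%-80s", "Created by scrambletrack")
  rec(function() {
    writeBin(1L, con, size = 4, endian = "little")
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(na), con, size = 4, endian = "little"),
      4)
  for (k in seq_len(nf)) {
    b <- boxDims(frames)[k, ]
    rec(function() writeBin(c(b[1], 90, b[2], 90, 90, b[3]), con, size = 8,
                            endian = "little"), 48)
    xyz <- frameCoords(frames, k)
    for (ax in 1:3)
      rec(function() writeBin(xyz[, ax], con, size = 4, endian = "little"),
          4 * na)
  }
  invisible(path)
}

# reinterpret a double as the integer bit pattern of its float32 value
.floatBits <- function(x) {
  raw <- writeBin(as.numeric(x), raw(), size = 4, endian = "little")
  readBin(raw, "integer", n = 1, size = 4, endian = "little")
}

.bitsFloat <- function(i) {
  raw <- writeBin(as.integer(i), raw(), size = 4, endian = "little")
  readBin(raw, "numeric", n = 1, size = 4, endian = "little")
}

#' Read a DCD trajectory
#'
#' @param path DCD file.
#' @param n_atoms expected atom count (checked against the header).
#' @return a [FrameSet-class] with times in ns.
#' @export
readDCD <- function(path, n_atoms = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  int1 <- function() readBin(con, "integer", 1, size = 4, endian = "little")
  expectRec <- function(n) {
    m <- int1()
    if (!identical(m, as.integer(n)))
      stop("malformed DCD record marker (expected ", n, ", got ", m, ")")
  }
  expectRec(84)
  magic <- readChar(con, 4, useBytes = TRUE)
  if (magic != "CORD") stop("not a DCD file (magic '", magic, "')")
  icntrl <- readBin(con, "integer", 20, size = 4, endian = "little")
  expectRec(84)
  nf <- icntrl[1]
  delta_ps <- .bitsFloat(icntrl[10])
  has_cell <- icntrl[11] == 1L
  tlen <- int1()
  ntitle <- int1()
  readChar(con, 80 * ntitle, useBytes = TRUE)
  expectRec(tlen)
  expectRec(4)
  na <- int1()
  expectRec(4)
  if (!is.null(n_atoms) && na != n_atoms)
    stop("atom count mismatch: topology has ", n_atoms,
         ", trajectory has ", na)
  coords <- array(NA_real_, c(na, 3, nf))
  box <- matrix(NA_real_, nf, 3)
  for (k in seq_len(nf)) {
    if (has_cell) {
      expectRec(48)
      cell <- readBin(con, "numeric", 6, size = 8, endian = "little")
      expectRec(48)
      box[k, ] <- cell[c(1, 3, 6)]
    }
    for (ax in 1:3) {
      expectRec(4 * na)
      coords[, ax, k] <- readBin(con, "numeric", na, size = 4,
                                 endian = "little")
      expectRec(4 * na)
    }
  }
  t0 <- icntrl[2] * delta_ps / 1000
  time <- t0 + (seq_len(nf) - 1) * icntrl[3] * delta_ps / 1000
  FrameSet(coords, box, time)
}
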