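# OpenDX (.dx) export of volumetric maps, the format VMD and PyMOL load for
# isosurface rendering.  Data values run with z fastest (the DX scalar-field
# convention).

#' Write an OccupancyGrid in OpenDX format
#'
#' Metadata entries (normalisation mode, bulk density, contour level, ...)
#' are written as `#` comment lines so downstream tools can recover the
#' provenance of the map.
#'
#' @param grid an [OccupancyGrid-class].
#' @param path output `.dx` file.
#' @export
writeDX <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- grid@dims
  writeLines(sprintf("# OpenDX density map written by scrambletrack"), con)
  writeLines(sprintf("# mode: %s", grid@mode), con)
  md <- grid@metadata
  for (nm in names(md))
    if (is.atomic(md[[nm]]) && length(md[[nm]]) == 1L)
      writeLines(sprintf("# %s: %s", nm, format(md[[nm]])), con)
  writeLines(sprintf("object 1 class gridpositions counts %d %d %d",
                     d[1], d[2], d[3]), con)
  writeLines(sprintf("origin %.6f %.6f %.6f", grid@origin[1],
                     grid@origin[2], grid@origin[3]), con)
  e <- grid@voxelEdge
  writeLines(sprintf("delta %.6f 0 0\ndelta 0 %.6f 0\ndelta 0 0 %.6f",
                     e, e, e), con)
  writeLines(sprintf("object 2 class gridconnections counts %d %d %d",
                     d[1], d[2], d[3]), con)
  n <- prod(d)
  writeLines(sprintf(
    "object 3 class array type double rank 0 items %d data follows", n), con)
  # z fastest: permute (x,y,z) array so z varies first in the flat vector
  v <- aperm(grid@values, c(3, 2, 1))
  flat <- as.vector(v)
  pad <- (3 - length(flat) %% 3) %% 3
  if (pad) flat <- c(flat, rep(NA_real_, pad))
  m <- matrix(flat, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r)
    paste(sprintf("%.6g", r[!is.na(r)]), collapse = " "))
  writeLines(lines, con)
  writeLines(c("attribute \"dep\" string \"positions\"",
               "object \"density\" class field",
               "component \"positions\" value 1",
               "component \"connections\" value 2",
               "component \"data\" value 3"), con)
  invisible(path)
}

#' Read an OpenDX scalar map written by [writeDX()]
#'
#' @param path `.dx` file.
#' @return an [OccupancyGrid-class]; `#`-comment metadata is restored as
#'   character strings.
#' @export
readDX <- function(path) {
  lines <- readLines(path)
  com <- lines[startsWith(lines, "#")]
  md <- list()
  for (l in com) {
    m <- regmatches(l, regexec("^# ([^:]+): (.*)$", l))[[1]]
    if (length(m) == 3) md[[m[2]]] <- m[3]
  }
  mode <- if (!is.null(md$mode)) md$mode else "fraction_of_frames"
  md$mode <- NULL
  g1 <- grep("^object 1 class gridpositions", lines, value = TRUE)[1]
  d <- as.integer(strsplit(sub(".*counts ", "", g1), " ")[[1]])
  org <- as.numeric(strsplit(sub("^origin ", "",
                    grep("^origin", lines, value = TRUE)[1]), " +")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  e <- as.numeric(strsplit(sub("^delta ", "", deltas[1]), " +")[[1]])[1]
  i3 <- grep("^object 3 class array", lines)
  n <- prod(d)
  vals <- as.numeric(unlist(strsplit(trimws(
    lines[(i3 + 1):length(lines)][seq_len(ceiling(n / 3))]), " +")))
  stopifnot(length(vals) == n)
  arr <- aperm(array(vals, c(d[3], d[2], d[1])), c(3, 2, 1))
  new("OccupancyGrid", origin = org, voxelEdge = e, dims = d,
      values = arr, mode = mode, metadata = md)
}
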