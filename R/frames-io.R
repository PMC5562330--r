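## Frame-stack and voltage-trace I/O.
##
## Stacks travel as multi-page grayscale 32-bit float TIFF (one page per
## frame, values in uM) or as delimited-text matrices. Reading goes through
## tiff::readTIFF, which returns IEEE float samples unscaled. Writing uses
## the package's own minimal baseline TIFF encoder because [Ca] values in uM
## routinely exceed 1 and must be stored as raw float32 without rescaling.

## Encode matrices as a little-endian baseline TIFF: one IFD per page,
## single strip, SampleFormat = IEEE float, no compression.
.writeFloatTiff <- function(frames, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  nPages <- length(frames)
  h <- nrow(frames[[1]]); wd <- ncol(frames[[1]])
  bytesPerPage <- h * wd * 4L
  nEntries <- 10L
  ifdSize <- 2L + nEntries * 12L + 4L
  dataStart <- 8L
  ifdStart <- dataStart + nPages * bytesPerPage
  ## header
  writeBin(charToRaw("II"), con)
  w16(42L)
  w32(ifdStart)
  ## pixel data, row-major within each page
  for (fr in frames)
    writeBin(as.vector(t(fr)), con, size = 4, endian = "little")
  ## IFD chain
  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count)
    if (type == 3L) { w16(value); w16(0L) } else w32(value)
  }
  for (p in seq_len(nPages)) {
    w16(nEntries)
    entry(256L, 4L, 1L, wd)                               # ImageWidth
    entry(257L, 4L, 1L, h)                                # ImageLength
    entry(258L, 3L, 1L, 32L)                              # BitsPerSample
    entry(259L, 3L, 1L, 1L)                               # Compression: none
    entry(262L, 3L, 1L, 1L)                               # Photometric: min-is-black
    entry(273L, 4L, 1L, dataStart + (p - 1L) * bytesPerPage) # StripOffsets
    entry(277L, 3L, 1L, 1L)                               # SamplesPerPixel
    entry(278L, 4L, 1L, h)                                # RowsPerStrip
    entry(279L, 4L, 1L, bytesPerPage)                     # StripByteCounts
    entry(339L, 3L, 1L, 3L)                               # SampleFormat: IEEE float
    w32(if (p < nPages) ifdStart + p * ifdSize else 0L)
  }
  invisible(NULL)
}

## Parse one delimited text matrix (comma or whitespace separated), with an
## optional single non-numeric header line.
.parseTextMatrix <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(NULL)
  splitRow <- function(s) strsplit(trimws(s), "[,;[:space:]]+")[[1]]
  first <- suppressWarnings(as.numeric(splitRow(lines[1])))
  if (anyNA(first)) {
    lines <- lines[-1]
    if (length(lines) == 0L) return(NULL)
  }
  rows <- lapply(lines, function(s) {
    v <- suppressWarnings(as.numeric(splitRow(s)))
    if (anyNA(v)) stop("malformed numeric row: ", s)
    v
  })
  ncols <- unique(vapply(rows, length, 1L))
  if (length(ncols) != 1L)
    stop("rows of a text matrix must have equal length")
  do.call(rbind, rows)
}

## Split a text file into frames at blank lines; each block is one matrix.
.readTextFrames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(c(TRUE, blank[-length(blank)] & !blank[-1]))
  grp[blank] <- NA
  blocks <- split(lines[!blank], grp[!blank])
  frames <- lapply(blocks, .parseTextMatrix)
  frames[!vapply(frames, is.null, TRUE)]
}

.isTiffPath <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)

#' Load a frame stack from TIFF or delimited text
#'
#' Accepts a multi-page grayscale floating-point TIFF (one page per frame),
#' a delimited text file of one or more matrices separated by blank lines,
#' or a directory of such text files (read in lexicographic order, one or
#' more frames each). Values are interpreted as [Ca] in uM; no unit
#' auto-detection is performed.
#'
#' @param path file or directory to read.
#' @param dtMs frame interval in ms (default 5).
#' @param voxelEdgeNm voxel edge length in nm (default 100).
#' @param periodicX wrap-around flag for the column dimension.
#' @return a validated \code{\link{FrameStack}}.
#' @examples
#' fs <- FrameStack(array(runif(160), c(4, 4, 10)))
#' tf <- tempfile(fileext = ".tif")
#' writeStack(fs, tf)
#' fs2 <- loadStack(tf)
#' stopifnot(all.equal(frameData(fs), frameData(fs2), tolerance = 1e-6))
#' @export
loadStack <- function(path, dtMs = 5, voxelEdgeNm = 100, periodicX = FALSE) {
  if (!file.exists(path))
    stop("cannot read stack: no such file or directory: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, full.names = TRUE))
    files <- files[!dir.exists(files)]
    if (length(files) == 0L) stop("directory contains no frame files: ", path)
    frames <- unlist(lapply(files, .readTextFrames), recursive = FALSE)
  } else if (.isTiffPath(path)) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e) stop("unreadable TIFF: ",
                                               conditionMessage(e)))
    frames <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1, drop = TRUE]  # ignore extra channels
      p
    })
  } else {
    frames <- .readTextFrames(path)
  }
  if (length(frames) == 0L) stop("no frames found in ", path)
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L)
    stop("inconsistent frame shapes in ", path)
  vals <- unlist(frames, use.names = FALSE)
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("stack contains non-finite values")
  if (any(vals < 0))
    stop("stack contains negative [Ca] values")
  FrameStack(frames, dtMs = dtMs, voxelEdgeNm = voxelEdgeNm,
             periodicX = periodicX)
}

#' Write a frame stack as multi-page 32-bit float TIFF
#'
#' One grayscale page per frame, IEEE float samples in uM, uncompressed.
#' \code{loadStack(writeStack(s))} reproduces \code{s} to 32-bit float
#' precision; calibration metadata (dt, voxel edge) is not stored in the
#' file and must travel alongside it.
#'
#' @param stack a \code{\link{FrameStack}}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeStack <- function(stack, path) {
  if (!is(stack, "FrameStack")) stop("stack must be a FrameStack")
  validObject(stack)
  d <- stack@data
  frames <- lapply(seq_len(dim(d)[3]), function(i) d[, , i, drop = TRUE])
  frames <- lapply(frames, function(f) {
    if (is.null(dim(f))) matrix(f, nrow = dim(d)[1]) else f
  })
  ok <- tryCatch({ .writeFloatTiff(frames, path); TRUE },
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e)))
  invisible(path)
}

#' Load a membrane-potential trace from two-column delimited text
#'
#' Expects rows of \code{time_ms, Vm_mV} (comma or whitespace separated),
#' with an optional single header line. Times must be strictly increasing.
#'
#' @param path file to read.
#' @return a validated \code{\link{VoltageTrace}}.
#' @export
loadVoltage <- function(path) {
  if (!file.exists(path)) stop("cannot read voltage trace: ", path)
  m <- .parseTextMatrix(readLines(path, warn = FALSE))
  if (is.null(m) || ncol(m) != 2L)
    stop("voltage trace must have two columns (t_ms, vm_mV)")
  VoltageTrace(m[, 1], m[, 2])
}

#' Write a voltage trace as two-column delimited text
#' @param trace a \code{\link{VoltageTrace}}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeVoltage <- function(trace, path) {
  if (!is(trace, "VoltageTrace")) stop("trace must be a VoltageTrace")
  utils::write.table(
    data.frame(t_ms = trace@tMs, vm_mV = trace@vmMv),
    path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
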