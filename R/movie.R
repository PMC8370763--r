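#' Acquisition metadata for a mass-photometry movie
#'
#' Bundles the acquisition parameters that travel with a movie stack: the
#' effective frame rate, the effective pixel size, and the on-camera
#' averaging/binning factors already applied to the stored frames.
#'
#' @param frame_rate_hz Effective frame rate in Hz (after any frame
#'   averaging). Must be positive.
#' @param pixel_size_nm Effective pixel edge length in nm (after any spatial
#'   binning). Must be positive.
#' @param frame_avg Number of raw camera frames averaged per stored frame
#'   (integer, >= 1).
#' @param bin_px Spatial binning factor already applied (integer, >= 1).
#' @param units Free-text tag describing the intensity normalization.
#'
#' @return An object of class `movie_metadata` (a named list).
#' @examples
#' movie_metadata(frame_rate_hz = 500, pixel_size_nm = 70.2,
#'                frame_avg = 2, bin_px = 3)
#' @export
movie_metadata <- function(frame_rate_hz, pixel_size_nm, frame_avg = 1L,
                           bin_px = 1L, units = "normalized") {
  stopifnot(is.numeric(frame_rate_hz), length(frame_rate_hz) == 1L,
            is.numeric(pixel_size_nm), length(pixel_size_nm) == 1L)
  if (!is.finite(frame_rate_hz) || frame_rate_hz <= 0)
    stop("frame_rate_hz must be a positive finite number")
  if (!is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("pixel_size_nm must be a positive finite number")
  frame_avg <- as.integer(frame_avg)
  bin_px <- as.integer(bin_px)
  if (is.na(frame_avg) || frame_avg < 1L) stop("frame_avg must be >= 1")
  if (is.na(bin_px) || bin_px < 1L) stop("bin_px must be >= 1")
  structure(list(frame_rate_hz = as.numeric(frame_rate_hz),
                 pixel_size_nm = as.numeric(pixel_size_nm),
                 frame_avg = frame_avg, bin_px = bin_px,
                 units = as.character(units)),
            class = "movie_metadata")
}

#' Movie stack with metadata
#'
#' A movie is a 3-D array of normalized detector intensity indexed
#' `[row, col, frame]` plus a [movie_metadata()] record. Background pixels
#' sit near 1.0; a landing particle produces a small persistent dip.
#'
#' @param stack Numeric 3-D array `[row, col, frame]`; all values finite.
#' @param metadata A `movie_metadata` object.
#'
#' @return An object of class `mp_movie`.
#' @export
mp_movie <- function(stack, metadata) {
  if (!is.array(stack) || length(dim(stack)) != 3L)
    stop("stack must be a 3-D array [row, col, frame]")
  if (dim(stack)[3] < 1L) stop("movie must contain at least one frame")
  if (!inherits(metadata, "movie_metadata"))
    stop("metadata must be a movie_metadata object")
  bad <- which(!is.finite(stack))
  if (length(bad)) {
    fr <- ((bad[1] - 1L) %/% (dim(stack)[1] * dim(stack)[2])) + 1L
    stop(sprintf("stack contains %d non-finite pixel(s); first in frame %d",
                 length(bad), fr))
  }
  structure(list(stack = stack, metadata = metadata), class = "mp_movie")
}

#' @export
print.mp_movie <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("<mp_movie> %d x %d px, %d frames @ %g Hz, %g nm/px\n",
              d[1], d[2], d[3], x$metadata$frame_rate_hz,
              x$metadata$pixel_size_nm))
  invisible(x)
}

#' @export
dim.mp_movie <- function(x) dim(x$stack)

n_frames <- function(movie) dim(movie$stack)[3]

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

required_meta_fields <- c("frame_rate_hz", "pixel_size_nm", "frame_avg",
                          "bin_px", "units")

#' Write a movie to disk
#'
#' Writes the stack as a multi-page 32-bit float TIFF (or raw float32 binary
#' for a `.bin` path) plus a JSON metadata sidecar next to it. The written
#' representation round-trips bit-exactly through [read_movie()] for float32
#' data.
#'
#' @param movie An `mp_movie`.
#' @param path Output path ending in `.tif`/`.tiff` or `.bin`.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "mp_movie"))
  d <- dim(movie$stack)
  ext <- tolower(tools::file_ext(path))
  # store as float32: quantize once so read-back is an exact round-trip
  st <- float32_round(movie$stack)
  if (ext %in% c("tif", "tiff")) {
    ok <- try(write_tiff_float32(st, path), silent = TRUE)
    if (inherits(ok, "try-error")) stop("cannot write TIFF: ", path)
  } else if (ext == "bin") {
    con <- try(file(path, "wb"), silent = TRUE)
    if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
    on.exit(close(con), add = TRUE)
    writeBin(as.vector(st), con, size = 4L, endian = "little")
  } else stop("unsupported movie container: .", ext)
  meta <- unclass(movie$metadata)
  meta$shape <- as.integer(d)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}


# Minimal uncompressed multi-page float32 (SampleFormat IEEEFP) TIFF
# writer. The tiff package reads such files natively but only writes
# integer [0,1] storage, which cannot hold normalized intensities near 1
# losslessly; round-trips are verified against tiff::readTIFF in the tests.
write_tiff_float32 <- function(stack, path) {
  d <- dim(stack)
  w <- d[2]; h <- d[1]; npages <- d[3]
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  u16 <- function(x) writeBin(as.integer(x), con, size = 2L,
                              endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4L,
                              endian = "little")
  strip_bytes <- w * h * 4L
  ifd_bytes <- 2L + 10L * 12L + 4L
  data_off <- function(p) 8L + (p - 1L) * strip_bytes
  ifd_off <- function(p) 8L + npages * strip_bytes + (p - 1L) * ifd_bytes
  writeChar("II", con, nchars = 2, eos = NULL)
  u16(42L)
  u32(ifd_off(1L))
  for (p in seq_len(npages))                    # scanline (row-major) order
    writeBin(as.vector(t(stack[, , p])), con, size = 4L, endian = "little")
  entry <- function(tag, type, value) {         # type 3 SHORT, 4 LONG
    u16(tag); u16(type); u32(1L)
    if (type == 3L) { u16(value); u16(0L) } else u32(value)
  }
  for (p in seq_len(npages)) {
    u16(10L)
    entry(256L, 4L, w)                          # ImageWidth
    entry(257L, 4L, h)                          # ImageLength
    entry(258L, 3L, 32L)                        # BitsPerSample
    entry(259L, 3L, 1L)                         # Compression: none
    entry(262L, 3L, 1L)                         # Photometric: BlackIsZero
    entry(273L, 4L, data_off(p))                # StripOffsets
    entry(277L, 3L, 1L)                         # SamplesPerPixel
    entry(278L, 4L, h)                          # RowsPerStrip
    entry(279L, 4L, strip_bytes)                # StripByteCounts
    entry(339L, 3L, 3L)                         # SampleFormat: IEEE float
    u32(if (p < npages) ifd_off(p + 1L) else 0L)
  }
  invisible(path)
}

# round-trip doubles through float32 representation
float32_round <- function(x) {
  v <- readBin(writeBin(as.vector(as.numeric(x)), raw(), size = 4L),
               "numeric", n = length(x), size = 4L)
  if (is.array(x)) array(v, dim(x)) else v
}

#' Read a movie from disk
#'
#' Reads a multi-page float TIFF or raw float32 binary written by
#' [write_movie()], together with its JSON metadata sidecar. Every metadata
#' field must be present in the sidecar; nothing is defaulted silently.
#'
#' @param path Path to the `.tif`/`.tiff`/`.bin` file.
#' @return An `mp_movie`.
#' @export
read_movie <- function(path) {
  if (!file.exists(path)) stop("movie file not found: ", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("metadata sidecar not found: ", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  missing <- setdiff(required_meta_fields, names(meta))
  if (length(missing))
    stop("metadata sidecar lacks required field(s): ",
         paste(missing, collapse = ", "))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- c(dim(pages[[1]]), length(pages))
    stack <- array(0, d)
    for (t in seq_along(pages)) stack[, , t] <- pages[[t]]
  } else if (ext == "bin") {
    if (is.null(meta$shape) || length(meta$shape) != 3L)
      stop("raw binary movie requires a 3-element 'shape' in the sidecar")
    d <- as.integer(meta$shape)
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    v <- readBin(con, "numeric", n = prod(d), size = 4L, endian = "little")
    if (length(v) != prod(d))
      stop("stack size on disk does not match sidecar shape")
    stack <- array(v, d)
  } else stop("unsupported movie container: .", ext)
  if (!is.null(meta$shape) && !all(dim(stack) == as.integer(meta$shape)))
    stop("stack shape on disk does not match sidecar shape")
  mp_movie(stack, movie_metadata(meta$frame_rate_hz, meta$pixel_size_nm,
                                 meta$frame_avg, meta$bin_px, meta$units))
}

#' Temporal frame averaging and spatial pixel binning
#'
#' Applies the acquisition-time preprocessing used to reduce data volume:
#' consecutive blocks of `frame_avg` frames are averaged into one stored
#' frame, and each `bin_px` x `bin_px` pixel block is replaced by its mean.
#' Trailing frames/rows/cols that do not fill a complete block are cropped
#' (with a warning). Metadata is updated accordingly: the frame rate is
#' divided by `frame_avg` and the pixel size multiplied by `bin_px`.
#'
#' @param movie An `mp_movie` at raw resolution.
#' @param frame_avg Frames averaged per output frame (>= 1).
#' @param bin_px Spatial binning factor (>= 1).
#' @return A new, smaller `mp_movie`.
#' @examples
#' m <- mp_movie(array(1, c(6, 6, 4)),
#'               movie_metadata(1000, 23.4))
#' m2 <- preprocess_movie(m, frame_avg = 2, bin_px = 3)
#' dim(m2)            # 2 x 2 x 2
#' m2$metadata$frame_rate_hz   # 500
#' m2$metadata$pixel_size_nm   # 70.2
#' @export
preprocess_movie <- function(movie, frame_avg, bin_px) {
  stopifnot(inherits(movie, "mp_movie"))
  frame_avg <- as.integer(frame_avg); bin_px <- as.integer(bin_px)
  if (is.na(frame_avg) || frame_avg < 1L) stop("frame_avg must be >= 1")
  if (is.na(bin_px) || bin_px < 1L) stop("bin_px must be >= 1")
  st <- movie$stack
  d <- dim(st)
  nr2 <- d[1] %/% bin_px; nc2 <- d[2] %/% bin_px; nf2 <- d[3] %/% frame_avg
  if (nr2 < 1L || nc2 < 1L || nf2 < 1L)
    stop("movie too small for the requested averaging/binning")
  if (nr2 * bin_px != d[1] || nc2 * bin_px != d[2] || nf2 * frame_avg != d[3])
    warning(sprintf(
      "cropping trailing remainder: %d row(s), %d col(s), %d frame(s)",
      d[1] - nr2 * bin_px, d[2] - nc2 * bin_px, d[3] - nf2 * frame_avg))
  st <- st[seq_len(nr2 * bin_px), seq_len(nc2 * bin_px),
           seq_len(nf2 * frame_avg), drop = FALSE]
  if (bin_px > 1L) {
    # rows: (bin, nr2, nc, nf) -> mean over bin
    a <- array(st, c(bin_px, nr2, nc2 * bin_px, nf2 * frame_avg))
    st <- colMeans(a)                       # (nr2, nc, nf)
    # cols: (nr2, bin, nc2, nf) -> bring bin first
    a <- array(st, c(nr2, bin_px, nc2, nf2 * frame_avg))
    st <- colMeans(aperm(a, c(2, 1, 3, 4))) # (nr2, nc2, nf)
  }
  if (frame_avg > 1L) {
    a <- array(st, c(nr2, nc2, frame_avg, nf2))
    st <- colMeans(aperm(a, c(3, 1, 2, 4))) # (nr2, nc2, nf2)
  }
  st <- array(st, c(nr2, nc2, nf2))
  md <- movie$metadata
  mp_movie(st, movie_metadata(md$frame_rate_hz / frame_avg,
                              md$pixel_size_nm * bin_px,
                              md$frame_avg * frame_avg,
                              md$bin_px * bin_px, md$units))
}
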