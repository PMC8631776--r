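#' Read a time-ordered image stack
#'
#' Reads either a multi-page TIFF/OME-TIFF (`.tif`, `.tiff`) or a raw
#' little-endian float32 binary (any other extension) with a mandatory
#' JSON sidecar describing the array shape. Frames are returned in
#' acquisition (page/file) order; the reader never reorders, drops or
#' duplicates frames.
#'
#' Metadata is taken from the sidecar when present. Missing fields fall
#' back to documented defaults (`sampling_rate_hz` 4.4 for LSCI / 0.5
#' for 2-PM, `pixel_size_um` 1.0, `time_origin_s` 0, `modality`
#' `"lsci"`), each with a warning, so that a run can never silently
#' depend on unstated acquisition parameters.
#'
#' @param path Path to the stack file.
#' @param metadata_path Optional path to the JSON sidecar. Defaults to
#'   `paste0(path, ".json")` when that file exists.
#' @return A list with `frames` (numeric array `time x rows x cols`)
#'   and `metadata` (a [stack_metadata()]).
#' @seealso [write_stack()]
#' @export
read_stack <- function(path, metadata_path = NULL) {
  if (!file.exists(path)) {
    stop("stack file not found: ", path, call. = FALSE)
  }
  if (is.null(metadata_path)) {
    cand <- paste0(path, ".json")
    if (file.exists(cand)) metadata_path <- cand
  }
  side <- list()
  if (!is.null(metadata_path)) {
    if (!file.exists(metadata_path)) {
      stop("metadata sidecar not found: ", metadata_path, call. = FALSE)
    }
    side <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  }
  is_tiff <- grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)
  if (is_tiff) {
    # as.is = TRUE keeps integer samples unscaled but is rejected for
    # float images, which are already returned unscaled by default
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                      error = function(e) tiff::readTIFF(path, all = TRUE))
    if (!is.list(pages)) pages <- list(pages)
    dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      stop("TIFF pages disagree in size", call. = FALSE)
    }
    frames <- array(NA_real_, c(length(pages), dims[1, 1], dims[2, 1]))
    for (k in seq_along(pages)) {
      p <- pages[[k]]
      if (length(dim(p)) == 3) p <- p[, , 1]  # first channel only
      frames[k, , ] <- p
    }
  } else {
    if (is.null(side$shape)) {
      stop("raw binary stacks require a JSON sidecar with a 'shape' field",
           call. = FALSE)
    }
    shp <- as.integer(side$shape)
    if (length(shp) != 3 || any(shp <= 0)) {
      stop("sidecar 'shape' must be three positive integers (T, rows, cols)",
           call. = FALSE)
    }
    n <- prod(shp)
    nbytes <- file.size(path)
    if (nbytes != 4 * n) {
      stop(sprintf(
        "raw stack size mismatch: sidecar shape implies %d bytes, file has %d",
        4 * n, nbytes), call. = FALSE)
    }
    con <- file(path, "rb")
    on.exit(close(con))
    v <- readBin(con, what = "numeric", n = n, size = 4, endian = "little")
    # file layout is C order (cols fastest, then rows, then time)
    frames <- aperm(array(v, c(shp[3], shp[2], shp[1])), c(3, 2, 1))
  }
  md <- metadata_from_sidecar(side)
  list(frames = frames, metadata = md)
}

metadata_from_sidecar <- function(side) {
  modality <- side$modality
  if (is.null(modality)) {
    warning("sidecar missing 'modality'; assuming 'lsci'", call. = FALSE)
    modality <- "lsci"
  }
  rate <- side$sampling_rate_hz
  if (is.null(rate)) {
    rate <- if (modality == "lsci") 4.4 else 0.5
    warning(sprintf("sidecar missing 'sampling_rate_hz'; using default %g Hz",
                    rate), call. = FALSE)
  }
  px <- side$pixel_size_um
  if (is.null(px)) {
    warning("sidecar missing 'pixel_size_um'; using default 1.0 um",
            call. = FALSE)
    px <- 1
  }
  t0 <- side$time_origin_s
  if (is.null(t0)) t0 <- 0
  stack_metadata(sampling_rate_hz = rate, pixel_size_um = px,
                 time_origin_s = t0, modality = modality)
}

#' Write a stack with its metadata sidecar
#'
#' Writes either a raw little-endian float32 binary (default; exact
#' round trip at float32 precision) or an uncompressed float32
#' multi-page TIFF, plus a JSON sidecar carrying shape and acquisition
#' metadata. The TIFF is written by a minimal internal encoder because
#' the linked `tiff` library only encodes integer sample formats; pages
#' are IEEE float32, readable by any standard TIFF reader.
#'
#' @param frames Numeric array `time x rows x cols`.
#' @param path Output path; a `.tif`/`.tiff` extension selects TIFF.
#' @param metadata A [stack_metadata()].
#' @return `path`, invisibly.
#' @export
write_stack <- function(frames, path, metadata) {
  stopifnot(length(dim(frames)) == 3)
  validate_stack_metadata(metadata)
  if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) {
    write_tiff_float32(frames, path)
  } else {
    con <- file(path, "wb")
    v <- as.vector(aperm(frames, c(3, 2, 1)))  # C order on disk
    writeBin(v, con, size = 4, endian = "little")
    close(con)
  }
  side <- list(shape = dim(frames),
               sampling_rate_hz = metadata$sampling_rate_hz,
               pixel_size_um = metadata$pixel_size_um,
               time_origin_s = metadata$time_origin_s,
               modality = metadata$modality)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# Minimal uncompressed multi-page float32 TIFF encoder (little-endian,
# one strip per page, SampleFormat = IEEE float). Kept deliberately
# small; correctness is asserted against independent readers in the
# test suite.
write_tiff_float32 <- function(frames, path) {
  nt <- dim(frames)[1]; h <- dim(frames)[2]; w <- dim(frames)[3]
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header: II, magic 42, offset of first IFD
  writeBin(charToRaw("II"), con)
  w2(42L)
  data_bytes <- 4 * h * w
  ifd_bytes <- 2 + 10 * 12 + 4
  # layout per page: [pixel data][IFD]; first IFD right after first page data
  page_start <- function(k) 8 + (k - 1) * (data_bytes + ifd_bytes)
  w4(page_start(1) + data_bytes)
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3) { w2(value); w2(0L) } else w4(value)
  }
  for (k in seq_len(nt)) {
    # rows top to bottom, row-major
    writeBin(as.vector(t(frames[k, , ])), con, size = 4, endian = "little")
    w2(10L)  # entry count
    entry(256L, 3L, 1L, w)            # ImageWidth
    entry(257L, 3L, 1L, h)            # ImageLength
    entry(258L, 3L, 1L, 32L)          # BitsPerSample
    entry(259L, 3L, 1L, 1L)           # Compression: none
    entry(262L, 3L, 1L, 1L)           # Photometric: BlackIsZero
    entry(273L, 4L, 1L, page_start(k))        # StripOffsets
    entry(277L, 3L, 1L, 1L)           # SamplesPerPixel
    entry(278L, 3L, 1L, h)            # RowsPerStrip
    entry(279L, 4L, 1L, data_bytes)   # StripByteCounts
    entry(339L, 3L, 1L, 3L)           # SampleFormat: IEEE float
    w4(if (k < nt) page_start(k + 1) + data_bytes else 0L)
  }
  invisible(path)
}
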