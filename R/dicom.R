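# Minimal DICOM import: single-frame grayscale, explicit VR little endian.
# Covers what a radiograph export needs -- Rows/Columns, PixelSpacing,
# BitsAllocated, PixelRepresentation, Rescale slope/intercept, PixelData.
# Anything else (multi-frame, color, implicit VR, compressed transfer
# syntaxes) is rejected explicitly rather than guessed at.

.dcm_uint <- function(raw) sum(as.integer(raw) * 256^(seq_along(raw) - 1))

#' Import a single-frame grayscale DICOM radiograph
#'
#' Reads an explicit-VR little-endian DICOM file and returns a [image2d()]
#' whose spacing comes from the PixelSpacing attribute (row mm, col mm) and
#' whose intensities have the rescale slope/intercept applied
#' (`value = slope * stored + intercept`). Files without PixelSpacing are an
#' error: physical areas must never rest on an assumed 1 mm default.
#'
#' @param path path to a DICOM file.
#' @return A `limb_image`.
#' @export
import_dicom <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 132 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  pos <- 133L
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  while (pos + 7L <= length(bytes)) {
    group <- .dcm_uint(bytes[pos:(pos + 1L)])
    elem <- .dcm_uint(bytes[(pos + 2L):(pos + 3L)])
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported DICOM encoding (expected explicit VR little endian)")
    if (vr %in% long_vrs) {
      len <- .dcm_uint(bytes[(pos + 8L):(pos + 11L)])
      vstart <- pos + 12L
    } else {
      len <- .dcm_uint(bytes[(pos + 6L):(pos + 7L)])
      vstart <- pos + 8L
    }
    if (vr == "SQ") stop("DICOM sequences are not supported")
    value <- if (len > 0) bytes[vstart:(vstart + len - 1L)] else raw(0)
    key <- sprintf("%04x,%04x", group, elem)
    tags[[key]] <- list(vr = vr, value = value)
    pos <- vstart + len
  }
  ts <- tags[["0002,0010"]]
  if (!is.null(ts)) {
    uid <- rawToChar(ts$value[ts$value != as.raw(0)])
    if (trimws(uid) != "1.2.840.10008.1.2.1")
      stop("unsupported transfer syntax: ", trimws(uid),
           " (only explicit VR little endian is supported)")
  }
  get_us <- function(key) if (is.null(tags[[key]])) NULL else .dcm_uint(tags[[key]]$value[1:2])
  get_str <- function(key) if (is.null(tags[[key]])) NULL else trimws(rawToChar(tags[[key]]$value))
  nframes <- get_str("0028,0008")
  if (!is.null(nframes) && as.integer(nframes) > 1L)
    stop("multi-frame DICOM is not supported (NumberOfFrames = ", nframes, ")")
  samples <- get_us("0028,0002")
  if (!is.null(samples) && samples != 1L)
    stop("only grayscale (SamplesPerPixel = 1) DICOM is supported")
  rows <- get_us("0028,0010"); cols <- get_us("0028,0011")
  if (is.null(rows) || is.null(cols)) stop("DICOM missing Rows/Columns")
  spacing_str <- get_str("0028,0030")
  if (is.null(spacing_str))
    stop("DICOM missing PixelSpacing (0028,0030); refusing to assume a default")
  spacing <- as.numeric(strsplit(spacing_str, "\\\\")[[1]])
  bits <- get_us("0028,0100"); if (is.null(bits)) bits <- 16L
  signed <- identical(get_us("0028,0103"), 1L)
  slope <- get_str("0028,1053"); slope <- if (is.null(slope)) 1 else as.numeric(slope)
  intercept <- get_str("0028,1052"); intercept <- if (is.null(intercept)) 0 else as.numeric(intercept)
  px <- tags[["7fe0,0010"]]
  if (is.null(px)) stop("DICOM missing PixelData")
  size <- bits %/% 8L
  if (!size %in% c(1L, 2L)) stop("unsupported BitsAllocated: ", bits)
  stored <- readBin(px$value, "integer", n = rows * cols, size = size,
                    signed = if (size == 1L) FALSE else signed, endian = "little")
  if (size == 2L && !signed) stored <- ifelse(stored < 0, stored + 65536, stored)
  # PixelData is row-major (first image row first); transpose into R layout
  values <- t(matrix(as.double(stored), nrow = cols, ncol = rows))
  image2d(slope * values + intercept, spacing = spacing)
}
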