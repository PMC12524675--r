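# Minimal NRRD support for 2D scalar grids. Only what label maps and
# radiographs need: dimension 2, raw or text encoding, little-endian,
# mandatory per-axis spacing (a missing spacing is an error, never assumed
# 1 mm). Fastest axis = matrix rows, matching R's column-major layout.

.nrrd_types <- list(
  "double" = list(what = "double", size = 8L, mode = "double"),
  "float"  = list(what = "double", size = 4L, mode = "double"),
  "int"    = list(what = "integer", size = 4L, mode = "integer"),
  "int32"  = list(what = "integer", size = 4L, mode = "integer"),
  "short"  = list(what = "integer", size = 2L, mode = "integer"),
  "uchar"  = list(what = "integer", size = 1L, mode = "integer")
)

#' Read a 2D NRRD file
#'
#' Parses the header, checks that per-axis spacing metadata is present
#' (`spacings:` or axis-aligned `space directions:`), and returns the grid in
#' (row, col) orientation with spacing ordered (row mm, col mm). Integer
#' sample types yield an integer matrix (label maps), floating types a double
#' matrix (images).
#'
#' @param path path to an NRRD file.
#' @return A list with `grid` (matrix), `spacing` (length-2 numeric), and
#'   `header` (named character vector of raw header fields).
#' @seealso [write_nrrd()], [read_image_nrrd()], [read_labelmap_nrrd()]
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[0-9]$", magic)) stop("not an NRRD file: ", path)
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("malformed NRRD: header not terminated")
    if (line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed NRRD header line: ", line)
    header[trimws(kv[1])] <- trimws(paste(kv[-1], collapse = ":"))
  }
  need <- function(key) {
    if (is.na(header[key])) stop("NRRD header missing required field: ", key)
    header[[key]]
  }
  if (as.integer(need("dimension")) != 2L)
    stop("only 2-dimensional NRRD grids are supported")
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  spacing <- nrrd_spacing(header)
  type <- .nrrd_types[[need("type")]]
  if (is.null(type)) stop("unsupported NRRD sample type: ", header[["type"]])
  enc <- need("encoding")
  n <- prod(sizes)
  if (enc %in% c("raw")) {
    endian <- if (!is.na(header["endian"])) header[["endian"]] else "little"
    vals <- readBin(con, what = type$what, n = n, size = type$size,
                    endian = endian, signed = type$size > 1L)
  } else if (enc %in% c("txt", "text", "ascii")) {
    vals <- scan(con, what = double(), n = n, quiet = TRUE)
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(vals) != n) stop("NRRD data truncated: expected ", n, " values")
  storage.mode(vals) <- type$mode
  list(grid = matrix(vals, nrow = sizes[1], ncol = sizes[2]),
       spacing = spacing, header = header)
}

nrrd_spacing <- function(header) {
  if (!is.na(header["spacings"])) {
    sp <- as.numeric(strsplit(trimws(header[["spacings"]]), "\\s+")[[1]])
    return(check_spacing(sp))
  }
  if (!is.na(header["space directions"])) {
    vecs <- regmatches(header[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", header[["space directions"]]))[[1]]
    if (length(vecs) == 2) {
      sp <- vapply(vecs, function(v) {
        xy <- as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
        sqrt(sum(xy^2))
      }, numeric(1), USE.NAMES = FALSE)
      return(check_spacing(sp))
    }
  }
  stop("NRRD header carries no pixel spacing ('spacings' or 'space directions'); ",
       "refusing to assume a default")
}

#' Write a 2D grid as NRRD
#'
#' @param grid numeric or integer matrix (rows are the fastest axis).
#' @param spacing length-2 positive numeric (row mm, col mm), written to the
#'   `spacings:` header field.
#' @param path output path.
#' @param encoding "raw" (binary, little-endian) or "text".
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(grid, spacing, path, encoding = c("raw", "text")) {
  encoding <- match.arg(encoding)
  grid <- as.matrix(grid)
  spacing <- check_spacing(spacing)
  type <- if (is.integer(grid)) "int32" else "double"
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           paste0("type: ", type),
           "dimension: 2",
           paste("sizes:", nrow(grid), ncol(grid)),
           paste("spacings:", format(spacing[1], digits = 17),
                 format(spacing[2], digits = 17)),
           paste0("encoding: ", if (encoding == "raw") "raw" else "text"),
           if (encoding == "raw") "endian: little",
           "")
  writeLines(hdr, con)
  if (encoding == "raw") {
    writeBin(as.vector(grid), con, size = if (type == "int32") 4L else 8L,
             endian = "little")
  } else {
    writeLines(paste(format(as.vector(grid), digits = 17), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname read_nrrd
#' @export
read_image_nrrd <- function(path) {
  x <- read_nrrd(path)
  image2d(x$grid, x$spacing)
}

#' @rdname read_nrrd
#' @param schema a [label_schema()] used to validate the codes.
#' @export
read_labelmap_nrrd <- function(path, schema = default_schema()) {
  x <- read_nrrd(path)
  g <- x$grid
  if (!is.integer(g)) {
    if (max(abs(g - round(g))) > 0) stop("mask NRRD contains non-integer codes")
    storage.mode(g) <- "integer"
  }
  labelmap(g, x$spacing, schema)
}
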