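#' 2D radiograph image with physical pixel spacing
#'
#' An `limb_image` is a rows x cols matrix of finite intensities together with
#' the physical size of one pixel, `spacing = c(row_mm, col_mm)`. The (row,
#' col) convention is 0-offset-free base R: `values[r, c]`, row spacing first.
#'
#' @param values numeric matrix of finite intensities.
#' @param spacing length-2 positive numeric, physical pixel size in mm per
#'   axis, ordered (row, col).
#' @return An object of class `limb_image` with elements `values` and
#'   `spacing`.
#' @examples
#' img <- image2d(matrix(runif(12), 3, 4), spacing = c(0.5, 0.5))
#' dim(img$values)
#' @export
image2d <- function(values, spacing = c(1, 1)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("image intensities must all be finite")
  spacing <- check_spacing(spacing)
  structure(list(values = values, spacing = spacing), class = "limb_image")
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2 || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be two positive finite values (row mm, col mm)")
  spacing
}

#' @export
print.limb_image <- function(x, ...) {
  cat(sprintf("<limb_image> %d x %d px, spacing (%g, %g) mm, range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), x$spacing[1], x$spacing[2],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Label schema for lower-limb region maps
#'
#' Maps ordered region names to integer codes and flags which regions count as
#' muscle. Code 0 is always the background. The default schema follows the
#' color-coded limb regions used in ground-truth annotation: bone,
#' subcutaneous fat, and five muscle regions (lateral, medial, posterior,
#' gluteal, calf). A four-muscle variant without the posterior thigh region is
#' available because both labelings occur in practice.
#'
#' @param names character vector of region names; the first must be
#'   "background".
#' @param codes integer codes, unique and non-negative; background must be 0.
#' @param muscle logical vector flagging the muscle regions.
#' @return A `limb_schema` data frame with columns `name`, `code`, `muscle`.
#' @examples
#' default_schema()
#' default_schema(n_muscles = 4)
#' @export
label_schema <- function(names, codes = seq_along(names) - 1L, muscle = FALSE) {
  codes <- as.integer(codes)
  if (anyDuplicated(codes) || any(codes < 0))
    stop("schema codes must be unique and non-negative")
  if (anyDuplicated(names)) stop("schema names must be unique")
  if (names[1] != "background" || codes[1] != 0L)
    stop("first schema entry must be background with code 0")
  muscle <- rep_len(muscle, length(names))
  if (muscle[1]) stop("background cannot be a muscle region")
  structure(data.frame(name = names, code = codes, muscle = muscle,
                       stringsAsFactors = FALSE),
            class = c("limb_schema", "data.frame"))
}

#' @rdname label_schema
#' @param n_muscles 5 (default; lateral, medial, posterior, gluteal, calf) or
#'   4 (drops the posterior thigh region).
#' @export
default_schema <- function(n_muscles = 5) {
  muscles <- switch(as.character(n_muscles),
    "5" = c("lateral", "medial", "posterior", "gluteal", "calf"),
    "4" = c("lateral", "medial", "gluteal", "calf"),
    stop("n_muscles must be 4 or 5"))
  nm <- c("background", "bone", "subcutaneous_fat", muscles)
  label_schema(nm, muscle = c(FALSE, FALSE, FALSE, rep(TRUE, length(muscles))))
}

#' Names of the muscle regions in a schema
#'
#' @param schema a [label_schema()].
#' @return Character vector of region names flagged as muscle.
#' @export
muscle_classes <- function(schema) schema$name[schema$muscle]

schema_code <- function(schema, name) {
  i <- match(name, schema$name)
  if (anyNA(i)) stop("unknown region name(s): ", paste(name[is.na(i)], collapse = ", "))
  schema$code[i]
}

#' Integer-coded label map aligned to an image grid
#'
#' @param codes integer matrix of class codes; every code must be listed in
#'   the schema.
#' @param spacing length-2 positive numeric (row mm, col mm).
#' @param schema a [label_schema()]; defaults to [default_schema()].
#' @return An object of class `limb_labelmap` with elements `codes`,
#'   `spacing`, `schema`.
#' @examples
#' lm <- labelmap(matrix(0L, 4, 4), c(1, 1))
#' @export
labelmap <- function(codes, spacing = c(1, 1), schema = default_schema()) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (anyNA(codes)) stop("label codes must not be NA")
  bad <- setdiff(unique(as.vector(codes)), schema$code)
  if (length(bad))
    stop("label codes not in schema: ", paste(bad, collapse = ", "))
  spacing <- check_spacing(spacing)
  structure(list(codes = codes, spacing = spacing, schema = schema),
            class = "limb_labelmap")
}

#' @export
print.limb_labelmap <- function(x, ...) {
  present <- x$schema$name[x$schema$code %in% unique(as.vector(x$codes))]
  cat(sprintf("<limb_labelmap> %d x %d px, spacing (%g, %g) mm\n  regions present: %s\n",
              nrow(x$codes), ncol(x$codes), x$spacing[1], x$spacing[2],
              paste(present, collapse = ", ")))
  invisible(x)
}

same_grid <- function(a, b) {
  ga <- if (inherits(a, "limb_image")) a$values else a$codes
  gb <- if (inherits(b, "limb_image")) b$values else b$codes
  identical(dim(ga), dim(gb))
}
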