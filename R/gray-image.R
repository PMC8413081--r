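#' Construct a grayscale image object
#'
#' A `gray_image` is an integer matrix of 8-bit gray values (0--255) with at
#' least 3 rows and 3 columns, the domain every operator in this package
#' works on. The 3x3 minimum exists so that the 3x3 neighborhood used by the
#' directional weight features is always defined.
#'
#' @param pixels Numeric or integer matrix; values must be whole numbers in
#'   `[0, 255]`.
#' @return An object of class `gray_image`: an integer matrix with the class
#'   attribute set.
#' @export
#' @examples
#' img <- gray_image(matrix(0:24, 5, 5) * 10)
#' dim(img)
gray_image <- function(pixels) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  if (nrow(pixels) < 3L || ncol(pixels) < 3L) {
    stop("gray_image must be at least 3x3", call. = FALSE)
  }
  if (anyNA(pixels)) stop("gray_image must not contain NA", call. = FALSE)
  v <- as.vector(pixels)
  if (any(v < 0 | v > 255)) {
    stop("gray values must lie in [0, 255]", call. = FALSE)
  }
  if (any(v != round(v))) {
    stop("gray values must be whole numbers; use normalize_gray() first",
         call. = FALSE)
  }
  m <- matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels))
  structure(m, class = c("gray_image", "matrix", "array"))
}

#' Test for / coerce to gray_image
#' @param x Object to test or coerce.
#' @return `is_gray_image()` a logical; `as_gray_image()` a `gray_image`.
#' @export
is_gray_image <- function(x) inherits(x, "gray_image")

#' @rdname is_gray_image
#' @export
as_gray_image <- function(x) {
  if (is_gray_image(x)) return(x)
  gray_image(as.matrix(x))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, range [%d, %d]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

# Strip the class so arithmetic happens on a plain numeric matrix.
pixel_matrix <- function(x) {
  m <- unclass(x)
  storage.mode(m) <- "double"
  m
}

#' Round half away from zero
#'
#' Rounding convention applied once at load/normalization time (base R
#' `round()` rounds half to even, which would make normalization depend on
#' parity).
#'
#' @param x Numeric vector or matrix.
#' @return `x` rounded to the nearest integer, ties away from zero.
#' @export
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Normalize an intensity matrix to the 8-bit gray domain
#'
#' Values already in `{0, ..., 255}` are left untouched (idempotence), so an
#' 8-bit image passes through bit-exactly. Anything else (e.g. 12/16-bit
#' scanner output) is min--max rescaled to `[0, 255]` and rounded half away
#' from zero. A constant out-of-range matrix maps to 0.
#'
#' @param m Numeric matrix of nonnegative intensities.
#' @return Integer matrix with values in `[0, 255]`.
#' @export
normalize_gray <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  v <- as.vector(m)
  if (anyNA(v)) stop("intensities must not contain NA", call. = FALSE)
  if (all(v >= 0 & v <= 255 & v == round(v))) {
    return(matrix(as.integer(v), nrow(m), ncol(m)))
  }
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    out <- matrix(0L, nrow(m), ncol(m))
  } else {
    out <- matrix(as.integer(round_half_up((v - lo) / (hi - lo) * 255)),
                  nrow(m), ncol(m))
  }
  out
}

#' Read a grayscale image from PNG or TIFF
#'
#' Multi-channel images are collapsed by the unweighted channel mean (alpha
#' channels are dropped first), then rounded half away from zero. TIFF files
#' are read at native bit depth and min--max rescaled to `[0, 255]` when they
#' exceed the 8-bit range; PNG files are read as 8-bit.
#'
#' @param path Path to an existing `.png`, `.tif`/`.tiff` file.
#' @param format Optional explicit format, `"png"` or `"tiff"`; inferred from
#'   the file extension when missing.
#' @return A [gray_image].
#' @export
load_gray <- function(path, format = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: file '%s' does not exist", path),
         call. = FALSE)
  }
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, png = "png", tif = , tiff = "tiff",
                     stop(sprintf("unrecognized image extension '%s' for '%s'",
                                  ext, path), call. = FALSE))
  }
  format <- match.arg(format, c("png", "tiff"))
  arr <- switch(format,
    png  = tryCatch(png::readPNG(path), error = function(e)
      stop(sprintf("failed to decode PNG '%s': %s", path, conditionMessage(e)),
           call. = FALSE)),
    tiff = tryCatch(tiff::readTIFF(path, as.is = TRUE), error = function(e)
      stop(sprintf("failed to decode TIFF '%s': %s", path,
                   conditionMessage(e)), call. = FALSE))
  )
  if (length(arr) == 0L) stop("zero-sized image", call. = FALSE)
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc %in% c(2L, 4L)) nc <- nc - 1L        # drop alpha
    arr <- apply(arr[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  # readPNG returns [0,1]; readTIFF(as.is=) returns native integers.
  if (format == "png") arr <- arr * 255
  gray_image(normalize_gray(round_half_up(arr)))
}

#' Write a grayscale image to PNG or TIFF
#'
#' 8-bit lossless: `load_gray(save_gray(x, p))` reproduces `x` exactly.
#'
#' @param image A [gray_image] (or matrix coercible to one).
#' @param path Output path ending in `.png`, `.tif` or `.tiff`; the parent
#'   directory must exist.
#' @return `path`, invisibly.
#' @export
save_gray <- function(image, path) {
  image <- as_gray_image(image)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop(sprintf("cannot write image: directory '%s' does not exist", dir),
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  m <- pixel_matrix(image) / 255
  switch(ext,
    png = png::writePNG(m, path),
    tif = , tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L),
    stop(sprintf("unrecognized image extension '%s'", ext), call. = FALSE)
  )
  invisible(path)
}

#' Quantize an edge response to an 8-bit image
#'
#' Responses are real-valued; writing them out requires quantization. Values
#' are clipped to `[0, 255]` and rounded half away from zero — the only place
#' the package quantizes intermediate arithmetic.
#'
#' @param values Numeric matrix (e.g. an [edge_response]).
#' @return A [gray_image].
#' @export
clip_to_gray <- function(values) {
  m <- pixel_matrix(values)
  gray_image(matrix(as.integer(round_half_up(pmin(pmax(m, 0), 255))),
                    nrow(m), ncol(m)))
}
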