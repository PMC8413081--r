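#' Flat grayscale morphology and morphological gradient operators
#'
#' Erosion takes the per-pixel minimum of the image over the structuring
#' element support; dilation the per-pixel maximum over the support
#' reflected through the anchor (the standard convention, so the duality
#' `dilate(x, se) = 255 - erode(255 - x, reflect_se(se))` holds exactly).
#' Borders are handled by replicate padding by default — on flat regions
#' this introduces no spurious gradient at the frame; reflect padding is
#' available via `border`.
#'
#' Because every structuring element contains its anchor, the operator
#' ordering `dilate >= close >= image >= open >= erode` holds pixelwise, and
#' all gradient operators built from differences along that chain are
#' nonnegative.
#'
#' @param image A [gray_image] or numeric matrix.
#' @param se A `struct_elem` from [make_structuring_element()].
#' @param border `"replicate"` (default) or `"reflect"`.
#' @return A numeric matrix of the same dimensions (min/max of integer
#'   inputs, so values stay in `[0, 255]` for true gray images).
#' @name morphology
NULL

# Shift-and-combine engine: for each offset, read the padded image shifted
# by that offset and fold with pmin/pmax. O(|support| * pixels).
morph_extremum <- function(m, offsets, fun, border) {
  R <- nrow(m); S <- ncol(m)
  pad <- max(1L, max(abs(offsets)))
  ri <- pad_index(R, pad, border)
  ci <- pad_index(S, pad, border)
  padded <- m[ri, ci, drop = FALSE]
  out <- NULL
  for (k in seq_len(nrow(offsets))) {
    dr <- offsets[k, 1]; dc <- offsets[k, 2]
    block <- padded[(pad + 1L + dr):(pad + R + dr),
                    (pad + 1L + dc):(pad + S + dc), drop = FALSE]
    out <- if (is.null(out)) block else fun(out, block)
  }
  out
}

# Index vector realizing replicate or reflect padding of length n by `pad`.
pad_index <- function(n, pad, border) {
  idx <- (1L - pad):(n + pad)
  if (border == "replicate") {
    pmin(pmax(idx, 1L), n)
  } else if (border == "reflect") {
    # reflect without repeating the border pixel: 2 1 | 1 2 3 ... (edge-mirrored)
    idx <- ifelse(idx < 1L, 1L - idx, idx)
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
    # guard tiny images against over-long reflections
    pmin(pmax(idx, 1L), n)
  } else {
    stop("`border` must be 'replicate' or 'reflect'", call. = FALSE)
  }
}

#' @rdname morphology
#' @export
erode <- function(image, se, border = "replicate") {
  m <- pixel_matrix(as_gray_matrix(image))
  morph_extremum(m, se$offsets, pmin, border)
}

#' @rdname morphology
#' @export
dilate <- function(image, se, border = "replicate") {
  m <- pixel_matrix(as_gray_matrix(image))
  morph_extremum(m, -se$offsets, pmax, border)
}

#' @rdname morphology
#' @export
open_ <- function(image, se, border = "replicate") {
  dilate(erode(image, se, border), se, border)
}

#' @rdname morphology
#' @export
close_ <- function(image, se, border = "replicate") {
  erode(dilate(image, se, border), se, border)
}

# Accept gray_image, edge_response, or bare matrix for internal chaining.
as_gray_matrix <- function(x) {
  if (is_gray_image(x)) return(unclass(x))
  if (inherits(x, "edge_response")) return(x$values)
  if (is.matrix(x)) return(x)
  stop("expected a gray_image or matrix", call. = FALSE)
}

#' Edge response container
#'
#' Per-pixel nonnegative gradient magnitude produced by one of the operators
#' `p1..p6`, `q1`, `q2`, `Q`, or the multiscale `MuQ`.
#'
#' @param values Nonnegative numeric matrix.
#' @param operator_tag Character label of the producing operator.
#' @return An `edge_response` (list with `values`, `operator_tag`).
#' @export
edge_response <- function(values, operator_tag = "unknown") {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (any(values < 0)) stop("edge response must be nonnegative", call. = FALSE)
  structure(list(values = values, operator_tag = operator_tag),
            class = "edge_response")
}

#' @export
print.edge_response <- function(x, ...) {
  cat(sprintf("<edge_response [%s] %d x %d, max %.3f>\n", x$operator_tag,
              nrow(x$values), ncol(x$values), max(x$values)))
  invisible(x)
}

#' Classical morphological gradient operators p1--p6
#'
#' The six traditional gradients built from erosion, dilation, opening and
#' closing:
#' \describe{
#'   \item{p1}{`dilate(g) - g` (external half-gradient)}
#'   \item{p2}{`g - erode(g)` (internal half-gradient)}
#'   \item{p3}{`dilate(g) - erode(g)` (full gradient; `p3 = p1 + p2`)}
#'   \item{p4}{`g - open(g)` (top-hat)}
#'   \item{p5}{`close(g) - g` (bottom-hat)}
#'   \item{p6}{`close(g) - open(g)`}
#' }
#' All are pointwise nonnegative by the morphological ordering chain on the
#' infinite lattice. On a finite image with replicate borders the chain can
#' break for p4--p6 in a thin frame at the image border when a *diagonal*
#' one-sided element clamps into a corner (axis-aligned and isotropic
#' elements are unaffected, as are all interior pixels); those differences
#' are clamped at zero so the response invariant holds.
#'
#' @inheritParams morphology
#' @param which Integer selector in `1:6`.
#' @return An [edge_response].
#' @export
gradient_p <- function(image, se, which, border = "replicate") {
  if (length(which) != 1L || !(which %in% 1:6)) {
    stop("`which` must be one of 1..6", call. = FALSE)
  }
  g <- pixel_matrix(as_gray_matrix(image))
  v <- switch(which,
    dilate(g, se, border) - g,
    g - erode(g, se, border),
    dilate(g, se, border) - erode(g, se, border),
    pmax(g - open_(g, se, border), 0),
    pmax(close_(g, se, border) - g, 0),
    pmax(close_(g, se, border) - open_(g, se, border), 0))
  edge_response(v, paste0("p", which))
}

#' Cascaded anti-noise gradient operators q1, q2
#'
#' Opening removes bright (salt) specks, closing dark (pepper) specks.
#' Cascading them before differencing yields gradients that do not fire on
#' isolated impulse noise:
#' \describe{
#'   \item{q1}{`open(close(g)) - erode(close(g))`}
#'   \item{q2}{`dilate(open(g)) - close(open(g))`}
#' }
#' Both differences are clamped at zero; with anchor-containing structuring
#' elements they are already nonnegative, so clamping is a guard only (a
#' warning is emitted if it ever fires).
#'
#' @inheritParams morphology
#' @param which Integer selector, 1 or 2.
#' @return An [edge_response].
#' @export
gradient_q <- function(image, se, which, border = "replicate") {
  if (length(which) != 1L || !(which %in% 1:2)) {
    stop("`which` must be 1 or 2", call. = FALSE)
  }
  g <- pixel_matrix(as_gray_matrix(image))
  v <- if (which == 1L) {
    cg <- close_(g, se, border)
    open_(cg, se, border) - erode(cg, se, border)
  } else {
    og <- open_(g, se, border)
    dilate(og, se, border) - close_(og, se, border)
  }
  if (any(v < 0)) {
    warning(sprintf("q%d produced %d negative pixels; clamped to 0",
                    which, sum(v < 0)))
    v[v < 0] <- 0
  }
  edge_response(v, paste0("q", which))
}

#' Convex-combination parameters for the combined operator
#'
#' @param kappa Weight on the pointwise maximum of q1 and q2 (dark-noise
#'   suppression side), in `[0, 1]`.
#' @param lambda Weight on the pointwise minimum (bright-noise suppression
#'   side); `kappa + lambda` must equal 1.
#' @return A list with class `operator_params`.
#' @export
operator_params <- function(kappa = 0.5, lambda = 1 - kappa) {
  if (kappa < 0 || kappa > 1 || lambda < 0 || lambda > 1) {
    stop("kappa and lambda must lie in [0, 1]", call. = FALSE)
  }
  if (abs(kappa + lambda - 1) > 1e-12) {
    stop("kappa + lambda must equal 1", call. = FALSE)
  }
  structure(list(kappa = kappa, lambda = lambda), class = "operator_params")
}

#' Combined anti-noise gradient operator Q
#'
#' Per pixel, `qmax = max(q1, q2)` and `qmin = min(q1, q2)`; the combined
#' response is the convex combination `Q = kappa * qmax + lambda * qmin`.
#' `qmax` emphasizes suppression of dark noise, `qmin` of bright noise;
#' `kappa = lambda = 0.5` (the default) weighs both equally, in which case
#' `Q = (q1 + q2) / 2`.
#'
#' @inheritParams morphology
#' @param params An [operator_params()].
#' @return An [edge_response] tagged `"Q"`.
#' @export
combined_Q <- function(image, se, params = operator_params(),
                       border = "replicate") {
  if (!inherits(params, "operator_params")) {
    params <- do.call(operator_params, as.list(params))
  }
  q1 <- gradient_q(image, se, 1L, border)$values
  q2 <- gradient_q(image, se, 2L, border)$values
  v <- params$kappa * pmax(q1, q2) + params$lambda * pmin(q1, q2)
  edge_response(v, "Q")
}
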