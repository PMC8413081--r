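#' Gray-difference direction features and structuring-element weights
#'
#' The 3x3 neighborhood of a pixel is labeled clockwise from the top:
#' ```
#'   d8 d1 d2
#'   d7 d0 d3
#'   d6 d5 d4
#' ```
#' with `d0` the center. Squared center-to-neighbor differences accumulated
#' over the whole image interior give per-direction gray-difference features;
#' normalizing them yields the weights used to blend the eight directional
#' edge responses. Opposite neighbors form four axes indexed `m = 1..4`:
#' `(d1,d5)` vertical, `(d2,d6)` NE--SW diagonal, `(d3,d7)` horizontal,
#' `(d4,d8)` SE--NW diagonal.
#'
#' @name directional_weights
NULL

# Offsets of d1..d8 in (row, col) relative to the center.
neighbor_offsets <- function() {
  matrix(c(-1L,  0L,   # d1 N
           -1L,  1L,   # d2 NE
            0L,  1L,   # d3 E
            1L,  1L,   # d4 SE
            1L,  0L,   # d5 S
            1L, -1L,   # d6 SW
            0L, -1L,   # d7 W
           -1L, -1L),  # d8 NW
         ncol = 2, byrow = TRUE,
         dimnames = list(paste0("d", 1:8), c("row", "col")))
}

# Sum over the interior of (d0 - d_x)^2 for one neighbor offset, vectorized.
sq_diff_sum <- function(m, off) {
  R <- nrow(m); S <- ncol(m)
  center <- m[2:(R - 1), 2:(S - 1), drop = FALSE]
  nb <- m[(2 + off[1]):(R - 1 + off[1]), (2 + off[2]):(S - 1 + off[2]),
          drop = FALSE]
  sum((center - nb)^2)
}

#' @describeIn directional_weights Per-neighbor squared-difference features
#'   `l1..l8` (the "gray mutation direction" features): `l_x` sums
#'   `(d0 - d_x)^2` over all interior pixels.
#' @param image A [gray_image] or numeric matrix, at least 3x3.
#' @return `fine_features()`: named numeric vector `l1..l8`.
#' @export
fine_features <- function(image) {
  m <- pixel_matrix(as_gray_matrix(image))
  if (nrow(m) < 3L || ncol(m) < 3L) {
    stop("image must be at least 3x3", call. = FALSE)
  }
  off <- neighbor_offsets()
  stats::setNames(vapply(1:8, function(x) sq_diff_sum(m, off[x, ]),
                         numeric(1)),
                  paste0("l", 1:8))
}

#' @describeIn directional_weights Per-axis features `h1..h4`: for axis `m`
#'   the sum of the two opposite neighbors' `l` features, i.e. the total
#'   squared gray difference along that axis.
#' @return `axis_features()`: named numeric vector `h1..h4`.
#' @export
axis_features <- function(image) {
  l <- fine_features(image)
  stats::setNames(c(l[1] + l[5], l[2] + l[6], l[3] + l[7], l[4] + l[8]),
                  paste0("h", 1:4))
}

#' @describeIn directional_weights Normalized axis weights
#'   `vQm = h_m / sum(h)`; a flat image (all `h = 0`) falls back to the
#'   uniform `0.25` each, since any convention is edge-free there.
#' @param h Nonnegative numeric vector of length 4 from [axis_features()].
#' @return `axis_weights()`: named numeric vector `vQ1..vQ4` summing to 1.
#' @export
axis_weights <- function(h) {
  if (length(h) != 4L) stop("`h` must have length 4", call. = FALSE)
  if (any(h < 0)) stop("axis features must be nonnegative", call. = FALSE)
  tot <- sum(h)
  v <- if (tot == 0) rep(0.25, 4) else h / tot
  stats::setNames(as.numeric(v), paste0("vQ", 1:4))
}

#' @describeIn directional_weights Split each axis weight between its two
#'   fine directions. The bookkeeping pairs each axis weight with a fixed
#'   consecutive pair of fine features:
#'   `v1 = l5/(l5+l6) * vQ3`, `v2 = l7/(l7+l8) * vQ4`,
#'   `v3 = l1/(l1+l2) * vQ1`, `v4 = l3/(l3+l4) * vQ2`, with complements
#'   `v5 = vQ3 - v1`, `v6 = vQ4 - v2`, `v7 = vQ1 - v3`, `v8 = vQ2 - v4`.
#'   A zero ratio denominator splits the axis weight 50/50. The
#'   complementary structure guarantees the conservation identities
#'   `v1+v5 = vQ3`, `v2+v6 = vQ4`, `v3+v7 = vQ1`, `v4+v8 = vQ2` and hence
#'   `sum(v) = 1`.
#' @param l Nonnegative numeric vector of length 8 from [fine_features()].
#' @param vQ Numeric vector of length 4 summing to 1.
#' @return `fine_weights()`: list of class `direction_weights` with
#'   `axis_weights` (`vQ1..vQ4`) and `fine_weights` (`v1..v8`).
#' @export
fine_weights <- function(l, vQ) {
  if (length(l) != 8L) stop("`l` must have length 8", call. = FALSE)
  if (length(vQ) != 4L) stop("`vQ` must have length 4", call. = FALSE)
  if (any(l < 0)) stop("fine features must be nonnegative", call. = FALSE)
  if (abs(sum(vQ) - 1) > 1e-9) stop("`vQ` must sum to 1", call. = FALSE)
  ratio <- function(a, b) if (l[a] + l[b] == 0) 0.5 else l[a] / (l[a] + l[b])
  v <- numeric(8)
  v[1] <- ratio(5, 6) * vQ[3]; v[5] <- vQ[3] - v[1]
  v[2] <- ratio(7, 8) * vQ[4]; v[6] <- vQ[4] - v[2]
  v[3] <- ratio(1, 2) * vQ[1]; v[7] <- vQ[1] - v[3]
  v[4] <- ratio(3, 4) * vQ[2]; v[8] <- vQ[2] - v[4]
  structure(
    list(axis_weights = stats::setNames(as.numeric(vQ), paste0("vQ", 1:4)),
         fine_weights = stats::setNames(v, paste0("v", 1:8))),
    class = "direction_weights")
}

#' @describeIn directional_weights Convenience wrapper: features and both
#'   weight sets for an image in one call.
#' @export
direction_weights <- function(image) {
  l <- fine_features(image)
  h <- axis_features(image)
  fine_weights(l, axis_weights(h))
}

#' @export
print.direction_weights <- function(x, ...) {
  cat("<direction_weights>\n  axis: ",
      paste(sprintf("%s=%.3f", names(x$axis_weights), x$axis_weights),
            collapse = " "),
      "\n  fine: ",
      paste(sprintf("%s=%.3f", names(x$fine_weights), x$fine_weights),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Weighted eight-direction combined edge response
#'
#' Computes the combined anti-noise gradient [combined_Q()] with each of the
#' eight directional structuring elements at the given scale, multiplies each
#' directional response by its image-driven weight and sums. Fine-direction
#' index `x = 1..8` maps to compass directions N, NE, E, SE, S, SW, W, NW
#' (the `d1..d8` clockwise-from-top layout). Weights are global — computed
#' once per image from the whole-interior features — not per pixel.
#'
#' @inheritParams morphology
#' @param scale Odd integer >= 3 passed to [make_structuring_element()].
#' @param params An [operator_params()].
#' @param weights Optional precomputed `direction_weights`; computed from
#'   `image` when missing.
#' @return An [edge_response] tagged `"wQ"`.
#' @export
weighted_directional_response <- function(image, scale,
                                          params = operator_params(),
                                          border = "replicate",
                                          weights = NULL) {
  if (is.null(weights)) weights <- direction_weights(image)
  v <- weights$fine_weights
  labels <- fine_direction_labels()
  acc <- NULL
  for (x in 1:8) {
    if (v[x] == 0) next
    se <- make_structuring_element(scale, labels[x])
    qx <- combined_Q(image, se, params, border)$values
    acc <- if (is.null(acc)) v[x] * qx else acc + v[x] * qx
  }
  if (is.null(acc)) {
    m <- as_gray_matrix(image)
    acc <- matrix(0, nrow(m), ncol(m))
  }
  edge_response(acc, "wQ")
}
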