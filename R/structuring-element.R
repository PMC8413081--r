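#' Directional and isotropic flat structuring elements
#'
#' The algorithm probes an image along eight compass directions with flat
#' (binary-support) structuring elements. At scale `s` (an odd integer, the
#' side of the bounding box) a directional element is a half-line of
#' `ceiling(s / 2)` pixels starting at the anchor and stepping along the
#' compass direction; the one-sided support keeps the eight directions
#' genuinely distinct (symmetric lines would collapse opposite directions
#' onto four axes). The isotropic element is the full `s x s` square.
#'
#' @param scale Odd integer >= 3; side length of the bounding box.
#' @param direction One of `"E"`, `"NE"`, `"N"`, `"NW"`, `"W"`, `"SW"`,
#'   `"S"`, `"SE"`, `"isotropic"`.
#' @return A `struct_elem`: list with `offsets` (integer matrix of
#'   (row, col) offsets relative to the anchor, anchor `(0,0)` always
#'   included), `scale`, and `direction`.
#' @export
#' @examples
#' make_structuring_element(3, "E")$offsets
#' nrow(make_structuring_element(5, "isotropic")$offsets)  # 25
make_structuring_element <- function(scale, direction = "isotropic") {
  if (length(scale) != 1L || scale != round(scale) || scale < 3 ||
      scale %% 2 == 0) {
    stop("`scale` must be an odd integer >= 3", call. = FALSE)
  }
  scale <- as.integer(scale)
  direction <- match.arg(direction, names(compass_steps()))
  if (direction == "isotropic") {
    m <- (scale - 1L) %/% 2L
    g <- expand.grid(dr = -m:m, dc = -m:m)
    off <- cbind(g$dr, g$dc)
  } else {
    step <- compass_steps()[[direction]]
    k <- 0:((scale + 1L) %/% 2L - 1L)       # ceiling(scale/2) pixels
    off <- cbind(k * step[1], k * step[2])
  }
  structure(
    list(offsets = matrix(as.integer(off), ncol = 2,
                          dimnames = list(NULL, c("row", "col"))),
         scale = scale, direction = direction),
    class = "struct_elem")
}

compass_steps <- function() {
  list(E  = c(0L, 1L),  NE = c(-1L, 1L),  N  = c(-1L, 0L), NW = c(-1L, -1L),
       W  = c(0L, -1L), SW = c(1L, -1L),  S  = c(1L, 0L),  SE = c(1L, 1L),
       isotropic = c(0L, 0L))
}

#' The eight compass direction labels, in fine-direction order
#'
#' Fine-direction index `x = 1..8` corresponds to the 3x3 neighbor layout
#' read clockwise from the top: N, NE, E, SE, S, SW, W, NW. This is the
#' order in which [direction_weights()] reports the eight weights and in
#' which [weighted_directional_response()] builds its structuring elements.
#'
#' @return Character vector of length 8.
#' @export
fine_direction_labels <- function() {
  c("N", "NE", "E", "SE", "S", "SW", "W", "NW")
}

#' Reflect a structuring element through its anchor
#'
#' @param se A `struct_elem`.
#' @return A `struct_elem` with every offset negated.
#' @export
reflect_se <- function(se) {
  stopifnot(inherits(se, "struct_elem"))
  se$offsets <- -se$offsets
  se
}

#' @export
print.struct_elem <- function(x, ...) {
  cat(sprintf("<struct_elem scale %d, direction %s, %d offsets>\n",
              x$scale, x$direction, nrow(x$offsets)))
  invisible(x)
}
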