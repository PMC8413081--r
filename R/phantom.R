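#' Synthetic MRI-like phantom specification
#'
#' Phantoms emulate single-slice MRI cross-sections as piecewise-constant
#' anatomical regions — nested ellipses, annuli and rectangles rasterized in
#' listed order (later shapes overwrite earlier ones) on a uniform
#' background — corrupted by bright ("salt", set to 255) and dark
#' ("pepper", set to 0) impulse noise followed by additive Gaussian noise.
#' The clean image, the noisy image and an exact ground-truth edge map are
#' returned together, so detection quality can be scored exactly.
#'
#' @param height,width Image dimensions in pixels (each >= 3).
#' @param shapes List of shape lists. Each shape has `kind` (`"ellipse"`,
#'   `"annulus"`, `"rectangle"`), `intensity` (0--255), and geometry:
#'   ellipses/annuli take `center = c(row, col)` and `radii = c(ry, rx)`
#'   (annuli additionally `inner = c(ry, rx)`); rectangles take
#'   `top_left = c(row, col)` and `extent = c(h, w)`.
#' @param background Background intensity (0--255).
#' @param salt_fraction,pepper_fraction Per-pixel corruption probabilities,
#'   each in `[0, 0.5]`.
#' @param gaussian_sigma Standard deviation of the additive Gaussian noise
#'   in gray levels, >= 0.
#' @param seed Integer seed; the phantom is a deterministic function of the
#'   spec, noise included.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 128L, width = 128L,
                         shapes = default_phantom_shapes(height, width),
                         background = 30,
                         salt_fraction = 0.025, pepper_fraction = 0.025,
                         gaussian_sigma = 5, seed = 1L) {
  if (height < 3 || width < 3) stop("phantom must be at least 3x3",
                                    call. = FALSE)
  if (salt_fraction < 0 || salt_fraction > 0.5 ||
      pepper_fraction < 0 || pepper_fraction > 0.5) {
    stop("noise fractions must lie in [0, 0.5]", call. = FALSE)
  }
  if (gaussian_sigma < 0) stop("gaussian_sigma must be >= 0", call. = FALSE)
  if (background < 0 || background > 255) {
    stop("background intensity must lie in [0, 255]", call. = FALSE)
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 shapes = shapes, background = background,
                 salt_fraction = salt_fraction,
                 pepper_fraction = pepper_fraction,
                 gaussian_sigma = gaussian_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default phantom anatomy
#'
#' A uterus-like cross-section: a large body ellipse, a darker inner cavity,
#' a bright annular wall segment, and a small rectangular insert — four
#' intensity plateaus giving closed curved and straight boundaries of the
#' kind uterine/placental MRI slices show.
#'
#' @param height,width Phantom dimensions the shapes are scaled to.
#' @return A list of shape lists for [phantom_spec()].
#' @export
default_phantom_shapes <- function(height = 128L, width = 128L) {
  cy <- (height + 1) / 2; cx <- (width + 1) / 2
  list(
    list(kind = "ellipse", center = c(cy, cx),
         radii = c(0.42 * height, 0.40 * width), intensity = 110),
    list(kind = "annulus", center = c(cy, cx),
         radii = c(0.30 * height, 0.28 * width),
         inner = c(0.22 * height, 0.20 * width), intensity = 190),
    list(kind = "ellipse", center = c(cy + 0.06 * height, cx),
         radii = c(0.14 * height, 0.12 * width), intensity = 70),
    list(kind = "rectangle",
         top_left = c(round(0.15 * height), round(0.60 * width)),
         extent = c(round(0.10 * height), round(0.16 * width)),
         intensity = 230)
  )
}

rasterize_shape <- function(canvas, shape) {
  R <- nrow(canvas); S <- ncol(canvas)
  it <- shape$intensity
  if (is.null(it) || it < 0 || it > 255) {
    stop("shape intensity must lie in [0, 255]", call. = FALSE)
  }
  rows <- matrix(seq_len(R), R, S)
  cols <- matrix(seq_len(S), R, S, byrow = TRUE)
  mask <- switch(shape$kind,
    ellipse = {
      d <- ((rows - shape$center[1]) / shape$radii[1])^2 +
           ((cols - shape$center[2]) / shape$radii[2])^2
      d <= 1
    },
    annulus = {
      do <- ((rows - shape$center[1]) / shape$radii[1])^2 +
            ((cols - shape$center[2]) / shape$radii[2])^2
      di <- ((rows - shape$center[1]) / shape$inner[1])^2 +
            ((cols - shape$center[2]) / shape$inner[2])^2
      do <= 1 & di > 1
    },
    rectangle = {
      r0 <- shape$top_left[1]; c0 <- shape$top_left[2]
      r1 <- r0 + shape$extent[1] - 1; c1 <- c0 + shape$extent[2] - 1
      if (r0 < 1 || c0 < 1 || r1 > R || c1 > S) {
        stop("rectangle out of bounds", call. = FALSE)
      }
      rows >= r0 & rows <= r1 & cols >= c0 & cols <= c1
    },
    stop(sprintf("unknown shape kind '%s'", shape$kind), call. = FALSE))
  if (shape$kind %in% c("ellipse", "annulus")) {
    lo_r <- shape$center[1] - shape$radii[1]
    hi_r <- shape$center[1] + shape$radii[1]
    lo_c <- shape$center[2] - shape$radii[2]
    hi_c <- shape$center[2] + shape$radii[2]
    if (lo_r < 0.5 || hi_r > R + 0.5 || lo_c < 0.5 || hi_c > S + 0.5) {
      stop("shape out of bounds", call. = FALSE)
    }
  }
  canvas[mask] <- it
  canvas
}

#' Ground-truth edge map of a piecewise-constant image
#'
#' A pixel is a boundary pixel when any of its 4-neighbors has a different
#' intensity.
#'
#' @param clean A [gray_image] or integer matrix.
#' @return Binary (0/1) integer matrix of the same dimensions.
#' @export
edge_truth_map <- function(clean) {
  boundary_map_4(as_gray_matrix(clean))
}

#' Generate a phantom
#'
#' Rasterizes the shapes, derives the exact edge map from the clean image,
#' then corrupts: salt (255), pepper (0), Gaussian noise (rounded half away
#' from zero, clipped to `[0, 255]`), all drawn from a single stream seeded
#' by `spec$seed` — identical specs give bit-identical phantoms. The global
#' RNG state is left untouched.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom`: `clean` and `noisy` ([gray_image]s)
#'   and `edge_truth` (0/1 integer matrix).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  canvas <- matrix(spec$background, spec$height, spec$width)
  for (sh in spec$shapes) canvas <- rasterize_shape(canvas, sh)
  clean <- gray_image(canvas)
  truth <- boundary_map_4(unclass(clean))
  noisy <- with_local_seed(spec$seed, {
    m <- pixel_matrix(clean)
    n <- length(m)
    u_salt <- stats::runif(n)
    m[u_salt < spec$salt_fraction] <- 255
    u_pepper <- stats::runif(n)
    m[u_pepper < spec$pepper_fraction] <- 0
    if (spec$gaussian_sigma > 0) {
      m <- m + stats::rnorm(n, 0, spec$gaussian_sigma)
    }
    gray_image(matrix(as.integer(round_half_up(pmin(pmax(m, 0), 255))),
                      nrow(m), ncol(m)))
  })
  structure(list(clean = clean, noisy = noisy, edge_truth = truth,
                 spec = spec),
            class = "phantom")
}

# 4-connectivity boundary: pixel differs from any of its N/S/E/W neighbors.
boundary_map_4 <- function(m) {
  R <- nrow(m); S <- ncol(m)
  e <- matrix(FALSE, R, S)
  dv <- m[-R, , drop = FALSE] != m[-1, , drop = FALSE]
  e[-R, ] <- e[-R, ] | dv
  e[-1, ] <- e[-1, ] | dv
  dh <- m[, -S, drop = FALSE] != m[, -1, drop = FALSE]
  e[, -S] <- e[, -S] | dh
  e[, -1] <- e[, -1] | dh
  matrix(as.integer(e), R, S)
}

# Run `expr` under a private RNG stream, restoring global state afterwards.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Precision/recall of a thresholded edge response
#'
#' Binarizes the response at `threshold` (strictly greater) and scores it
#' against a ground-truth edge map with a 1-pixel tolerance ring: a
#' predicted pixel is a true positive when a truth pixel lies within
#' Chebyshev distance 1, and a truth pixel counts as recalled when a
#' predicted pixel lies within distance 1. Morphological gradients are at
#' least one pixel thick, so exact-pixel matching would be uninformative.
#' An empty prediction has precision 0 by convention.
#'
#' @param response [edge_response] or numeric matrix.
#' @param truth Binary matrix of the same dimensions.
#' @param threshold Scalar; pixels with response strictly above it are
#'   predicted edges.
#' @return Named numeric vector `c(precision = , recall = )`.
#' @export
edge_map_score <- function(response, truth, threshold) {
  r <- as_gray_matrix(response)
  truth <- as.matrix(truth)
  check_same_dim(r, truth)
  pred <- r > threshold
  tr <- truth > 0
  if (!any(pred)) {
    return(c(precision = 0, recall = 0))
  }
  tr_d <- dilate_binary_3x3(tr)
  pred_d <- dilate_binary_3x3(pred)
  precision <- sum(pred & tr_d) / sum(pred)
  recall <- if (!any(tr)) 0 else sum(tr & pred_d) / sum(tr)
  c(precision = precision, recall = recall)
}

#' Precision of an edge response at a matched recall level
#'
#' Scans thresholds from the highest response value downward and returns
#' the [edge_map_score()] at the largest threshold whose recall reaches
#' `target` — the operating point used to compare operators at matched
#' recall (an operator that fires on noise pays in precision at the same
#' recall).
#'
#' @inheritParams edge_map_score
#' @param target Recall level to match, in `(0, 1]`.
#' @return Named numeric vector `c(precision = , recall = )`; zeros when no
#'   threshold reaches the target recall.
#' @export
precision_at_recall <- function(response, truth, target = 0.9) {
  r <- as_gray_matrix(response)
  thresholds <- sort(unique(as.vector(r)), decreasing = TRUE)
  for (th in thresholds) {
    sc <- edge_map_score(r, truth, th - 1e-9)
    if (sc[["recall"]] >= target) return(sc)
  }
  c(precision = 0, recall = 0)
}

# Chebyshev-1 dilation of a logical mask (3x3 square).
dilate_binary_3x3 <- function(mask) {
  se <- make_structuring_element(3L, "isotropic")
  morph_extremum(mask * 1, se$offsets, pmax, "replicate") > 0
}
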