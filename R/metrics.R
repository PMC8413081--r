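#' Image quality metrics: MSE, PSNR, SSIM
#'
#' The evaluation harness for processed-vs-reference image pairs. PSNR comes
#' in two dialects: the `"paper"` dialect uses `10 * log10(65536 / MSE)`
#' (peak power written as 256 x 256), the `"standard"` dialect
#' `10 * log10(255^2 / MSE)`; they differ by the constant
#' `10 * log10(65536 / 65025) ~ 0.034` dB. Identical images have `MSE = 0`
#' and PSNR `Inf`.
#'
#' @param a,b [gray_image]s (or numeric matrices) of equal dimensions.
#' @name quality_metrics
NULL

check_same_dim <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("dimension mismatch: %dx%d vs %dx%d",
                 nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
  }
}

#' @describeIn quality_metrics Mean squared pixel difference.
#' @return `mse()`: nonnegative scalar.
#' @export
mse <- function(a, b) {
  a <- pixel_matrix(as_gray_matrix(a)); b <- pixel_matrix(as_gray_matrix(b))
  check_same_dim(a, b)
  mean((a - b)^2)
}

#' @describeIn quality_metrics Peak signal-to-noise ratio in dB; `Inf` when
#'   the images are identical.
#' @param dialect `"paper"` (peak power 65536) or `"standard"` (peak power
#'   255^2).
#' @return `psnr()`: scalar dB (possibly `Inf`).
#' @export
psnr <- function(a, b, dialect = c("paper", "standard")) {
  dialect <- match.arg(dialect)
  e <- mse(a, b)
  if (e == 0) return(Inf)
  peak <- if (dialect == "paper") 65536 else 255^2
  10 * log10(peak / e)
}

#' @describeIn quality_metrics Structural similarity index. `"global"` mode
#'   treats the whole image as a single window; `"windowed"` averages 8x8
#'   sliding windows. Stabilizing constants are the standard
#'   `C1 = (0.01 * 255)^2`, `C2 = (0.03 * 255)^2`. Both modes return exactly
#'   1 for identical images.
#' @param mode `"global"` or `"windowed"`.
#' @return `ssim()`: scalar in `[-1, 1]`.
#' @export
ssim <- function(a, b, mode = c("global", "windowed")) {
  mode <- match.arg(mode)
  a <- pixel_matrix(as_gray_matrix(a)); b <- pixel_matrix(as_gray_matrix(b))
  check_same_dim(a, b)
  C1 <- (0.01 * 255)^2
  C2 <- (0.03 * 255)^2
  if (mode == "global") {
    return(ssim_window(a, b, C1, C2))
  }
  w <- 8L
  R <- nrow(a); S <- ncol(a)
  if (R < w || S < w) return(ssim_window(a, b, C1, C2))
  # box sums over all w x w windows via integral images
  n <- w * w
  sa  <- box_sum(a, w);  sb  <- box_sum(b, w)
  saa <- box_sum(a * a, w); sbb <- box_sum(b * b, w); sab <- box_sum(a * b, w)
  mua <- sa / n; mub <- sb / n
  # population (biased) moments, matching the single-window formula
  vara <- saa / n - mua^2
  varb <- sbb / n - mub^2
  cov  <- sab / n - mua * mub
  num <- (2 * mua * mub + C1) * (2 * cov + C2)
  den <- (mua^2 + mub^2 + C1) * (vara + varb + C2)
  mean(num / den)
}

ssim_window <- function(a, b, C1, C2) {
  mua <- mean(a); mub <- mean(b)
  vara <- mean((a - mua)^2)
  varb <- mean((b - mub)^2)
  cov <- mean((a - mua) * (b - mub))
  ((2 * mua * mub + C1) * (2 * cov + C2)) /
    ((mua^2 + mub^2 + C1) * (vara + varb + C2))
}

# Sum of every w x w window, computed with cumulative sums.
box_sum <- function(m, w) {
  cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed integral image
  cs <- t(cs)
  R <- nrow(m); S <- ncol(m)
  pad <- matrix(0, R + 1, S + 1)
  pad[-1, -1] <- cs
  i <- 1:(R - w + 1); j <- 1:(S - w + 1)
  pad[i + w, j + w, drop = FALSE] - pad[i, j + w, drop = FALSE] -
    pad[i + w, j, drop = FALSE] + pad[i, j, drop = FALSE]
}

#' Quality report for one processed/reference image pair
#'
#' @param processed,reference [gray_image]s of equal dimensions.
#' @param elapsed Optional wall-clock seconds to record (informational).
#' @return A one-row data.frame: `mse`, `psnr_paper`, `psnr_standard`,
#'   `ssim`, `elapsed_s`.
#' @export
quality_report <- function(processed, reference, elapsed = NA_real_) {
  data.frame(
    mse = mse(processed, reference),
    psnr_paper = psnr(processed, reference, "paper"),
    psnr_standard = psnr(processed, reference, "standard"),
    ssim = ssim(processed, reference, "windowed"),
    elapsed_s = elapsed)
}

#' Classification concordance table and accuracy
#'
#' Utility for comparing an image-based classification against a reference
#' standard, e.g. MRI placenta-previa typing (complete / partial / marginal)
#' against cesarean-section findings. `confusion_table()` builds the 3x3 (or
#' k x k) count matrix with rows = reference class, columns = assigned
#' class; `accuracy()` returns the percentage of cases on the diagonal.
#'
#' @param counts Square numeric matrix of nonnegative case counts.
#' @param classes Optional character vector of class labels.
#' @return `confusion_table()`: a `confusion_table` matrix.
#' @export
#' @examples
#' # 19/11/6 reference cases; two complete cases read as partial
#' tab <- confusion_table(matrix(c(17, 2, 0,
#'                                 0, 11, 0,
#'                                 0,  0, 6), 3, 3, byrow = TRUE),
#'                        c("complete", "partial", "marginal"))
#' accuracy(tab)  # 94.44
confusion_table <- function(counts, classes = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) {
    stop("confusion table must be square", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (sum(counts) <= 0) stop("confusion table must be non-empty", call. = FALSE)
  if (!is.null(classes)) dimnames(counts) <- list(reference = classes,
                                                  assigned = classes)
  structure(counts, class = c("confusion_table", "matrix", "array"))
}

#' @rdname confusion_table
#' @param table A `confusion_table`.
#' @return `accuracy()`: percentage in `[0, 100]` of diagonal cases.
#' @export
accuracy <- function(table) {
  if (!inherits(table, "confusion_table")) table <- confusion_table(table)
  100 * sum(diag(table)) / sum(table)
}
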