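# Independent brute-force oracles the implementation is checked against.
# These are deliberately written as plain double loops over pixels and
# support offsets, sharing no code with the package internals.

# Per-pixel neighborhood extremum with replicate padding.
oracle_morph <- function(m, offsets, fun) {
  R <- nrow(m); S <- ncol(m)
  out <- matrix(0, R, S)
  for (i in seq_len(R)) {
    for (j in seq_len(S)) {
      vals <- numeric(nrow(offsets))
      for (k in seq_len(nrow(offsets))) {
        ii <- min(max(i + offsets[k, 1], 1), R)
        jj <- min(max(j + offsets[k, 2], 1), S)
        vals[k] <- m[ii, jj]
      }
      out[i, j] <- fun(vals)
    }
  }
  out
}

oracle_erode <- function(m, se) oracle_morph(m, se$offsets, min)
oracle_dilate <- function(m, se) oracle_morph(m, -se$offsets, max)
oracle_open <- function(m, se) oracle_dilate(oracle_erode(m, se), se)
oracle_close <- function(m, se) oracle_erode(oracle_dilate(m, se), se)

# Straight-loop metric oracles.
oracle_mse <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    s <- s + (a[i, j] - b[i, j])^2
  }
  s / (nrow(a) * ncol(a))
}

oracle_psnr_paper <- function(a, b) 10 * log10(256 * 256 / oracle_mse(a, b))

oracle_ssim_global <- function(a, b) {
  C1 <- (0.01 * 255)^2; C2 <- (0.03 * 255)^2
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  va <- sum((a - ma)^2) / n; vb <- sum((b - mb)^2) / n
  cab <- sum((a - ma) * (b - mb)) / n
  (2 * ma * mb + C1) * (2 * cab + C2) /
    ((ma^2 + mb^2 + C1) * (va + vb + C2))
}

# Straight-loop direction features over the interior.
oracle_features <- function(m) {
  off <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
              c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  l <- numeric(8)
  for (i in 2:(nrow(m) - 1)) for (j in 2:(ncol(m) - 1)) {
    for (x in 1:8) {
      l[x] <- l[x] + (m[i, j] - m[i + off[[x]][1], j + off[[x]][2]])^2
    }
  }
  l
}

random_gray <- function(R, S, seed) {
  set.seed(seed)
  gray_image(matrix(sample(0:255, R * S, replace = TRUE), R, S))
}

all_directions <- c("E", "NE", "N", "NW", "W", "SW", "S", "SE", "isotropic")
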