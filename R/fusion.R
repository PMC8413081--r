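#' Configuration for the adaptive multiscale detection loop
#'
#' Scales are odd, `2m + 1` for `m = m_start, m_start + 1, ..., m_max`
#' (3x3, 5x5, 7x7, 9x9 by default). At each scale the weighted
#' eight-direction response is computed and a processed rendering of the
#' image is scored by PSNR against a reference; the loop stops when the
#' PSNR gate passes or `m_max` is reached, and all per-scale responses are
#' fused by their pointwise mean.
#'
#' @param m_start First half-width, integer >= 1 (scale `2 * m_start + 1`).
#' @param m_max Last half-width considered; default 4 (scale 9).
#' @param psnr_threshold PSNR gate in dB; default 30.
#' @param params An [operator_params()].
#' @param border Border mode for the morphology, see [morphology].
#' @param dialect PSNR dialect for the gate, `"paper"` or `"standard"`.
#' @param gate Gate polarity: `"stop_on_pass"` (default) stops scanning as
#'   soon as the per-scale PSNR exceeds the threshold;
#'   `"continue_on_pass"` keeps scanning while it exceeds it.
#' @param render Processed-image rendering used for the gate (and by the
#'   simulation harness): `"smooth"` (default) is the weighted directional
#'   open--close / close--open impulse-filtered rendering the cascaded
#'   gradients are built on; `"subtract"` subtracts the edge response from
#'   the input and clips to `[0, 255]`.
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(m_start = 1L, m_max = 4L, psnr_threshold = 30,
                          params = operator_params(), border = "replicate",
                          dialect = "paper",
                          gate = c("stop_on_pass", "continue_on_pass"),
                          render = c("smooth", "subtract")) {
  if (m_start < 1 || m_start != round(m_start)) {
    stop("`m_start` must be an integer >= 1", call. = FALSE)
  }
  if (m_max < m_start) stop("`m_max` must be >= `m_start`", call. = FALSE)
  if (is.na(psnr_threshold) || psnr_threshold < 0) {
    stop("`psnr_threshold` must be >= 0 (Inf allowed)", call. = FALSE)
  }
  if (!inherits(params, "operator_params")) {
    params <- do.call(operator_params, as.list(params))
  }
  structure(list(m_start = as.integer(m_start), m_max = as.integer(m_max),
                 psnr_threshold = psnr_threshold, params = params,
                 border = border, dialect = dialect,
                 gate = match.arg(gate), render = match.arg(render)),
            class = "fusion_config")
}

#' Fuse edge responses by their pointwise mean
#'
#' The multiscale fusion rule: the fused operator is the arithmetic mean of
#' the per-scale responses.
#'
#' @param responses Non-empty list of [edge_response]s (or matrices) with
#'   identical dimensions.
#' @return An [edge_response] tagged `"MuQ"`.
#' @export
fuse_mean <- function(responses) {
  if (length(responses) == 0L) {
    stop("`responses` must contain at least one response", call. = FALSE)
  }
  mats <- lapply(responses, as_gray_matrix)
  d <- dim(mats[[1]])
  for (m in mats) {
    if (!identical(dim(m), d)) {
      stop("all responses must share dimensions", call. = FALSE)
    }
  }
  edge_response(Reduce(`+`, mats) / length(mats), "MuQ")
}

#' Processed-image rendering at one scale
#'
#' The `"smooth"` rendering applies, for each of the eight directions, the
#' balanced impulse filter `(open(close(g)) + close(open(g))) / 2` — the two
#' denoised bases the cascaded gradients difference — and blends the eight
#' results with the directional weights. The `"subtract"` rendering is
#' `clip(g - response, 0, 255)`.
#'
#' @inheritParams weighted_directional_response
#' @param response [edge_response] at this scale (used by `"subtract"`).
#' @param render `"smooth"` or `"subtract"`.
#' @return A [gray_image].
#' @export
render_processed <- function(image, scale, response = NULL,
                             render = c("smooth", "subtract"),
                             border = "replicate", weights = NULL) {
  render <- match.arg(render)
  g <- pixel_matrix(as_gray_matrix(image))
  if (render == "subtract") {
    if (is.null(response)) stop("`response` required for render = 'subtract'",
                                call. = FALSE)
    return(clip_to_gray(g - as_gray_matrix(response)))
  }
  if (is.null(weights)) weights <- direction_weights(image)
  v <- weights$fine_weights
  labels <- fine_direction_labels()
  acc <- matrix(0, nrow(g), ncol(g))
  for (x in 1:8) {
    if (v[x] == 0) next
    se <- make_structuring_element(scale, labels[x])
    oc <- open_(close_(g, se, border), se, border)
    co <- close_(open_(g, se, border), se, border)
    acc <- acc + v[x] * (oc + co) / 2
  }
  clip_to_gray(acc)
}

#' Adaptive multiscale edge detection
#'
#' Runs the scale loop: for each half-width `m` starting at
#' `config$m_start`, builds the eight directional structuring elements at
#' scale `2m + 1`, computes the weighted directional response, renders the
#' processed image, and scores its PSNR against `reference` (the input
#' itself when no clean reference exists). Depending on the gate polarity
#' the loop stops on a passing PSNR or on reaching `m_max`. All per-scale
#' responses computed are fused by [fuse_mean()].
#'
#' @param image A [gray_image].
#' @param config A [fusion_config()].
#' @param reference Optional clean [gray_image] to score PSNR against
#'   (phantom experiments); defaults to `image`.
#' @return A `fusion_result`: list with `fused` ([edge_response] `"MuQ"`),
#'   `per_scale` (data.frame: `m`, `scale`, `psnr`), `responses` (list of
#'   per-scale [edge_response]s), `weights`, and `stop_reason`
#'   (`"threshold_met"` or `"m_max_reached"`).
#' @export
adaptive_detect <- function(image, config = fusion_config(),
                            reference = NULL) {
  image <- as_gray_image(as_gray_matrix(image))
  if (is.null(reference)) reference <- image
  weights <- direction_weights(image)
  responses <- list()
  rows <- list()
  stop_reason <- "m_max_reached"
  for (m in config$m_start:config$m_max) {
    scale <- 2L * m + 1L
    resp <- weighted_directional_response(image, scale,
                                          params = config$params,
                                          border = config$border,
                                          weights = weights)
    proc <- render_processed(image, scale, response = resp,
                             render = config$render, border = config$border,
                             weights = weights)
    p <- psnr(proc, reference, config$dialect)
    responses[[length(responses) + 1L]] <- resp
    rows[[length(rows) + 1L]] <- data.frame(m = m, scale = scale, psnr = p)
    passed <- p > config$psnr_threshold
    if ((config$gate == "stop_on_pass" && passed) ||
        (config$gate == "continue_on_pass" && !passed)) {
      stop_reason <- "threshold_met"
      break
    }
  }
  structure(list(fused = fuse_mean(responses),
                 per_scale = do.call(rbind, rows),
                 responses = responses,
                 weights = weights,
                 stop_reason = stop_reason),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("<fusion_result: %d scale(s) [%s], stop: %s>\n",
              nrow(x$per_scale), paste(x$per_scale$scale, collapse = ", "),
              x$stop_reason))
  invisible(x)
}
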