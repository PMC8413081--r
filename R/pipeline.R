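#' End-to-end commands: detect, simulate, evaluate
#'
#' The three commands behind the `morphedge` command-line script (installed
#' under `inst/scripts/`). Each is an ordinary R function so the whole
#' pipeline is scriptable from R as well; the CLI is a thin wrapper that
#' parses flags, calls these, and maps errors to exit codes (2 validation,
#' 3 I/O).
#'
#' @name pipeline
NULL

default_run_config <- function() {
  list(kappa = 0.5, lambda = 0.5, m_start = 1L, m_max = 4L,
       psnr_threshold = 30, border_mode = "replicate", dialect = "paper",
       gate = "stop_on_pass", render = "smooth", seed = 1L)
}

#' Read a YAML run configuration
#'
#' Recognized keys: `kappa`, `lambda`, `m_start`, `m_max`,
#' `psnr_threshold`, `border_mode`, `dialect`, `gate`, `render`, `seed`,
#' plus an optional `phantom` block (`height`, `width`, `background`,
#' `salt_fraction`, `pepper_fraction`, `gaussian_sigma`). Missing keys fall
#' back to built-in defaults; explicit arguments to the command functions
#' override the file.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
    }
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  if (is.null(cfg$lambda)) cfg$lambda <- 1 - cfg$kappa
  cfg
}

config_to_fusion <- function(cfg) {
  fusion_config(m_start = cfg$m_start, m_max = cfg$m_max,
                psnr_threshold = cfg$psnr_threshold,
                params = operator_params(cfg$kappa, cfg$lambda),
                border = cfg$border_mode, dialect = cfg$dialect,
                gate = cfg$gate, render = cfg$render)
}

#' @describeIn pipeline Detect edges in one image. Writes `fused.png`, one
#'   `scale_<s>.png` per scale visited (responses min--max stretched to
#'   8-bit for display), and `manifest.json` recording the configuration,
#'   per-scale PSNR gate values, weights and stop reason.
#' @param input Path to a PNG/TIFF image.
#' @param out_dir Output directory (created if missing).
#' @param config Named list as from [read_run_config()].
#' @return Invisibly, the `fusion_result`.
#' @export
morphedge_detect <- function(input, out_dir, config = read_run_config()) {
  img <- load_gray(input)
  fc <- config_to_fusion(config)
  res <- adaptive_detect(img, fc)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  save_gray(stretch_response(res$fused), file.path(out_dir, "fused.png"))
  for (i in seq_along(res$responses)) {
    s <- res$per_scale$scale[i]
    save_gray(stretch_response(res$responses[[i]]),
              file.path(out_dir, sprintf("scale_%d.png", s)))
  }
  manifest <- list(
    input = basename(input),
    config = config[c("kappa", "lambda", "m_start", "m_max",
                      "psnr_threshold", "border_mode", "dialect", "gate",
                      "render")],
    scales = res$per_scale$scale,
    psnr_gate = res$per_scale$psnr,
    weights = as.list(res$weights$fine_weights),
    axis_weights = as.list(res$weights$axis_weights),
    stop_reason = res$stop_reason)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

# Min-max stretch a response to the 8-bit range for display output.
stretch_response <- function(response) {
  v <- as_gray_matrix(response)
  hi <- max(v)
  if (hi == 0) return(clip_to_gray(v))
  clip_to_gray(v / hi * 255)
}

#' @describeIn pipeline Per-scale quality study on seeded phantoms: for each
#'   seed a phantom is generated and, at every scale `2m + 1` for
#'   `m = m_start..m_max` independently, the weighted directional response
#'   and the processed rendering are computed and scored (MSE / PSNR / SSIM
#'   against the clean phantom). Writes `metrics.csv` (one row per seed and
#'   scale) and `verdicts.json` with the fraction of seeds whose MSE is
#'   non-increasing and PSNR/SSIM non-decreasing across scales.
#' @param spec A [phantom_spec()]; its `seed` is replaced by each entry of
#'   `seeds`.
#' @param seeds Integer vector of phantom seeds.
#' @return Invisibly, a list with `metrics` (data.frame) and `verdicts`.
#' @export
morphedge_simulate <- function(spec = phantom_spec(), seeds = 1:10,
                               out_dir = NULL,
                               config = read_run_config()) {
  fc <- config_to_fusion(config)
  rows <- list()
  for (sd in seeds) {
    spec$seed <- as.integer(sd)
    ph <- generate_phantom(spec)
    weights <- direction_weights(ph$noisy)
    for (m in fc$m_start:fc$m_max) {
      scale <- 2L * m + 1L
      t0 <- proc.time()[["elapsed"]]
      resp <- weighted_directional_response(ph$noisy, scale,
                                            params = fc$params,
                                            border = fc$border,
                                            weights = weights)
      proc <- render_processed(ph$noisy, scale, response = resp,
                               render = fc$render, border = fc$border,
                               weights = weights)
      elapsed <- proc.time()[["elapsed"]] - t0
      qr <- quality_report(proc, ph$clean, elapsed)
      rows[[length(rows) + 1L]] <- cbind(data.frame(seed = sd, scale = scale),
                                         qr)
    }
  }
  metrics <- do.call(rbind, rows)
  verdicts <- trend_verdicts(metrics)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(verdicts, file.path(out_dir, "verdicts.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(metrics = metrics, verdicts = verdicts))
}

#' Per-seed monotone-trend verdicts of a simulation metrics table
#'
#' For each seed, checks whether MSE against the clean reference is
#' non-increasing in scale while PSNR and SSIM are non-decreasing, and
#' reports the fraction of seeds satisfying each.
#'
#' @param metrics Data frame from [morphedge_simulate()].
#' @return List with per-metric seed fractions and the seed count.
#' @export
trend_verdicts <- function(metrics) {
  by_seed <- split(metrics, metrics$seed)
  non_inc <- function(x) all(diff(x) <= 0)
  non_dec <- function(x) all(diff(x) >= 0)
  f <- function(fun, col) {
    mean(vapply(by_seed, function(d) fun(d[[col]][order(d$scale)]),
                logical(1)))
  }
  list(n_seeds = length(by_seed),
       mse_non_increasing = f(non_inc, "mse"),
       psnr_non_decreasing = f(non_dec, "psnr_paper"),
       ssim_non_decreasing = f(non_dec, "ssim"))
}

#' @describeIn pipeline Compare two images: prints and returns the
#'   [quality_report()].
#' @param reference,processed Paths to images of equal size.
#' @param dialect PSNR dialect for the printed summary.
#' @return Invisibly, the one-row quality data.frame.
#' @export
morphedge_evaluate <- function(processed, reference,
                               dialect = c("paper", "standard")) {
  dialect <- match.arg(dialect)
  a <- load_gray(processed)
  b <- load_gray(reference)
  qr <- quality_report(a, b)
  psnr_col <- if (dialect == "paper") "psnr_paper" else "psnr_standard"
  cat(sprintf("MSE: %.6g\nPSNR (%s): %.6g dB\nSSIM: %.6g\n",
              qr$mse, dialect, qr[[psnr_col]], qr$ssim))
  invisible(qr)
}
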