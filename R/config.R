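#' Pipeline configuration
#'
#' Bundles every tunable parameter of the vessel-analysis pipeline in one
#' validated object. Scales `sigmas` are expressed in physical units and
#' divided by `pixel_spacing` to obtain pixel-unit scales; with the default
#' `pixel_spacing = 1` they are interpreted directly in pixels.
#'
#' @param sigmas Strictly increasing positive vesselness scales. Default
#'   `c(0.5, 1, 1.5, 2, 2.5)`, the standard range for sub-epithelial vessels.
#' @param tau Response-uniformity parameter of the tubularity filter, in
#'   `(0, 1]`. Default 1.
#' @param pixel_spacing Physical length of one pixel; `sigmas / pixel_spacing`
#'   are the scales actually applied. Default 1 (sigmas in pixels).
#' @param polarity `"dark"` for dark vessels on a bright mucosa (the CE-NBI
#'   situation) or `"bright"` for the inverted convention.
#' @param channel How to collapse RGB input to one channel: `"green"`
#'   (hemoglobin contrast is strongest in green under narrow-band light) or
#'   `"luminance"` (Rec. 601 weights).
#' @param hysteresis_low,hysteresis_high Vesselness thresholds for hysteresis
#'   binarization, `0 < low < high <= 1`.
#' @param min_object_px Connected components smaller than this are removed
#'   from the vessel mask.
#' @param min_segment_len Minimum number of skeleton points for a traced
#'   centerline segment to be kept.
#' @param smooth_window Centered moving-average window (points) applied to
#'   segment coordinates before resampling.
#' @param resample_spacing Target uniform arc-length spacing (pixels) for
#'   segment resampling.
#' @param curvature_peak_threshold Curvature magnitude (1/px) above which a
#'   local maximum of |kappa| counts as a sharp turning point.
#' @param test_fraction Per-patient fraction of images assigned to the test
#'   subset by [split_by_patient()] (clamped to 2..5 images).
#' @param strict_majority Patient-level aggregation rule: if `TRUE` (default)
#'   a patient counts as correctly classified only when strictly more than
#'   half of the images are correct; `FALSE` gives the lenient >= reading.
#' @param seed Integer seed; mandatory for any stochastic operation.
#'
#' @return An object of class `cenbi_config` (a named list).
#' @examples
#' cfg <- pipeline_config(seed = 1)
#' cfg$sigmas
#' @export
pipeline_config <- function(sigmas = c(0.5, 1, 1.5, 2, 2.5),
                            tau = 1,
                            pixel_spacing = 1,
                            polarity = c("dark", "bright"),
                            channel = c("green", "luminance"),
                            hysteresis_low = 0.05,
                            hysteresis_high = 0.25,
                            min_object_px = 30,
                            min_segment_len = 10,
                            smooth_window = 5,
                            resample_spacing = 1,
                            curvature_peak_threshold = 0.15,
                            test_fraction = 0.2,
                            strict_majority = TRUE,
                            seed = NULL) {
  polarity <- match.arg(polarity)
  channel <- match.arg(channel)
  if (!length(sigmas) || any(!is.finite(sigmas)) || any(sigmas <= 0))
    stop("`sigmas` must be a non-empty vector of positive finite scales")
  if (is.unsorted(sigmas, strictly = TRUE))
    stop("`sigmas` must be strictly increasing")
  if (!is.finite(tau) || tau <= 0 || tau > 1)
    stop("`tau` must lie in (0, 1]")
  if (!is.finite(pixel_spacing) || pixel_spacing <= 0)
    stop("`pixel_spacing` must be positive")
  if (!(hysteresis_low > 0 && hysteresis_low < hysteresis_high &&
          hysteresis_high <= 1))
    stop("need 0 < hysteresis_low < hysteresis_high <= 1")
  if (min_object_px < 1) stop("`min_object_px` must be >= 1")
  if (min_segment_len < 3) stop("`min_segment_len` must be >= 3")
  if (smooth_window < 1 || smooth_window %% 2 != 1)
    stop("`smooth_window` must be an odd positive integer")
  if (resample_spacing <= 0) stop("`resample_spacing` must be positive")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("`test_fraction` must lie in (0, 1)")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(
    sigmas = as.numeric(sigmas), tau = tau, pixel_spacing = pixel_spacing,
    polarity = polarity, channel = channel,
    hysteresis_low = hysteresis_low, hysteresis_high = hysteresis_high,
    min_object_px = as.integer(min_object_px),
    min_segment_len = as.integer(min_segment_len),
    smooth_window = as.integer(smooth_window),
    resample_spacing = resample_spacing,
    curvature_peak_threshold = curvature_peak_threshold,
    test_fraction = test_fraction,
    strict_majority = isTRUE(strict_majority),
    seed = seed
  ), class = "cenbi_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; keys absent from the
#' file keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `cenbi_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config file must contain a key-value mapping")
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @export
print.cenbi_config <- function(x, ...) {
  cat("CE-NBI pipeline configuration\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = " ")))
  }
  invisible(x)
}

# internal: require a seed before any stochastic step
need_seed <- function(config) {
  if (is.null(config$seed))
    stop("this operation is stochastic: set `seed` in pipeline_config()")
  config$seed
}
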