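#' @name features
#' @title Geometric descriptors of vessel disorder
#' @description
#' Each traced centerline segment is summarized by six scalar descriptors
#' spanning two families: the consistency of the local vessel direction
#' (circular variance of the axial tangent direction; mean turning rate) and
#' the level of curvature (mean absolute curvature; density of sharp
#' curvature peaks; tortuosity; density of curvature inflections). The six
#' descriptors are pooled over all segments of an image with four statistics
#' each — length-weighted mean, length-weighted standard deviation, maximum
#' and 75th percentile — giving the fixed 24-dimensional feature vector.
NULL

# central differences with one-sided ends, unit parameter spacing
cdiff <- function(v) {
  n <- length(v)
  d <- numeric(n)
  d[1] <- v[2] - v[1]
  d[n] <- v[n] - v[n - 1]
  if (n > 2) d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / 2
  d
}

#' Unwrapped tangent-angle profile of a resampled segment
#'
#' The tangent angle `theta(s) = atan2(d row, d col)` is computed by central
#' differences of the coordinates and unwrapped so that consecutive samples
#' differ by less than pi.
#'
#' @param segment A resampled `vessel_segment` (>= 3 points, uniform spacing).
#' @return Numeric vector of angles (radians), one per point.
#' @export
tangent_profile <- function(segment) {
  pts <- segment$points
  if (nrow(pts) < 3) stop("tangent profile needs at least 3 points")
  theta <- atan2(cdiff(pts[, 1]), cdiff(pts[, 2]))
  # unwrap
  d <- diff(theta)
  jump <- round(d / (2 * pi))
  theta - c(0, cumsum(jump)) * 2 * pi
}

#' Signed curvature profile of a resampled segment
#'
#' `kappa = (x' y'' - y' x'') / (x'^2 + y'^2)^(3/2)` with derivatives by
#' central finite differences on the smoothed, resampled coordinates.
#'
#' @param segment A resampled `vessel_segment` (>= 5 points, uniform spacing).
#' @return Numeric vector of signed curvatures (1/px), one per point.
#' @export
curvature_profile <- function(segment) {
  pts <- segment$points
  if (nrow(pts) < 5) stop("curvature profile needs at least 5 points")
  x <- pts[, 2]; y <- pts[, 1]
  x1 <- cdiff(x); y1 <- cdiff(y)
  x2 <- cdiff(x1); y2 <- cdiff(y1)
  denom <- (x1^2 + y1^2)^1.5
  denom[denom < 1e-12] <- 1e-12
  (x1 * y2 - y1 * x2) / denom
}

#' Per-segment disorder descriptors
#'
#' @param segment A resampled `vessel_segment`.
#' @param curvature_peak_threshold Curvature magnitude (1/px) above which a
#'   local maximum of |kappa| counts as a sharp turning point.
#' @return A list of class `segment_descriptors`: `dir_var` (circular
#'   variance of the doubled tangent angles, in `[0, 1]` — doubling makes the
#'   statistic axial, i.e. insensitive to the arbitrary trace direction),
#'   `turn_rate` (rad/px), `curv_mean` (1/px), `peak_density` (1/px),
#'   `tortuosity` (>= 1; for a closed loop with zero chord it is set to
#'   `arc_length / spacing` and `closed = TRUE`), `inflect_density` (1/px),
#'   and `weight` (the arc length).
#' @export
segment_descriptors <- function(segment, curvature_peak_threshold = 0.15) {
  theta <- tangent_profile(segment)
  kappa <- curvature_profile(segment)
  L <- segment$arc_length
  if (!is.finite(L) || L <= 0) stop("segment has non-positive arc length")
  # axial circular variance: 1 - mean resultant length of doubled angles
  R <- Mod(mean(exp(2i * theta)))
  dir_var <- 1 - R
  turn_rate <- sum(abs(diff(theta))) / L
  ak <- abs(kappa)
  curv_mean <- mean(ak)
  n <- length(ak)
  peaks <- 0L
  if (n >= 3) {
    int <- 2:(n - 1)
    is_peak <- ak[int] > ak[int - 1] & ak[int] >= ak[int + 1] &
      ak[int] > curvature_peak_threshold
    peaks <- sum(is_peak)
  }
  pts <- segment$points
  chord <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
  closed <- chord < 1e-9
  spacing <- if (!is.null(segment$spacing) && is.finite(segment$spacing))
    segment$spacing else 1
  tortuosity <- if (closed) L / spacing else L / chord
  # dead zone: numerically-zero curvature must not generate sign changes
  sg <- sign(kappa)
  sg[abs(kappa) < 1e-6] <- 0
  sg <- sg[sg != 0]
  inflections <- if (length(sg) > 1) sum(diff(sg) != 0) else 0L
  structure(list(
    dir_var = dir_var, turn_rate = turn_rate, curv_mean = curv_mean,
    peak_density = peaks / L, tortuosity = tortuosity,
    inflect_density = inflections / L, weight = L, closed = closed
  ), class = "segment_descriptors")
}

descriptor_names <- c("dir_var", "turn_rate", "curv_mean",
                      "peak_density", "tortuosity", "inflect_density")
stat_names <- c("wmean", "wsd", "max", "p75")

#' Names of the 24 features, in their frozen order
#'
#' The order is descriptor-major: for each descriptor in
#' `dir_var, turn_rate, curv_mean, peak_density, tortuosity, inflect_density`
#' the four pooled statistics `wmean, wsd, max, p75`. This order is part of
#' the package contract; changing it is a breaking change.
#'
#' @return Character vector of length 24.
#' @export
feature_names <- function() {
  as.vector(t(outer(descriptor_names, stat_names, paste, sep = "_")))
}

#' Pool segment descriptors into the 24-feature vector
#'
#' For each of the six descriptors: arc-length-weighted mean, arc-length-
#' weighted (population) standard deviation, maximum, and unweighted 75th
#' percentile (linear interpolation between order statistics). An empty
#' segment collection yields the all-zero vector with attribute
#' `no_segments = TRUE`.
#'
#' @param descriptors A list of `segment_descriptors`.
#' @return Named numeric vector of length 24 (see [feature_names()]).
#' @export
extract_features <- function(descriptors) {
  nms <- feature_names()
  if (!length(descriptors)) {
    out <- stats::setNames(numeric(24), nms)
    attr(out, "no_segments") <- TRUE
    return(out)
  }
  w <- vapply(descriptors, `[[`, numeric(1), "weight")
  if (any(w <= 0)) stop("segment weights must be positive")
  out <- numeric(0)
  for (d in descriptor_names) {
    v <- vapply(descriptors, `[[`, numeric(1), d)
    wm <- sum(w * v) / sum(w)
    wsd <- sqrt(sum(w * (v - wm)^2) / sum(w))
    out <- c(out, wm, wsd, max(v),
             unname(stats::quantile(v, 0.75, type = 7)))
  }
  names(out) <- nms
  if (any(!is.finite(out))) stop("non-finite feature value")
  out
}

#' Full per-image feature extraction
#'
#' Runs the whole geometric pipeline on one grayscale image: multiscale
#' vessel enhancement, hysteresis binarization, mask cleaning,
#' skeletonization and tracing, smoothing/resampling, per-segment
#' descriptors and pooling into the 24-feature vector.
#'
#' @param image Numeric matrix in `[0, 1]` (see [load_image_gray()]).
#' @param config A [pipeline_config()].
#' @param return_intermediate If `TRUE`, also return the vesselness map,
#'   mask and segments.
#' @return The named 24-feature vector, or (with `return_intermediate`) a
#'   list `features`, `vesselness`, `mask`, `segments`.
#' @export
image_features <- function(image, config = pipeline_config(),
                           return_intermediate = FALSE) {
  vmap <- jerman_multiscale(image, config)
  mask <- binarize_vesselness(vmap, config$hysteresis_low,
                              config$hysteresis_high)
  mask <- clean_mask(mask, config$min_object_px)
  segs <- skeletonize_and_trace(mask, config$min_segment_len)
  segs <- lapply(segs, smooth_resample, window = config$smooth_window,
                 spacing = config$resample_spacing)
  segs <- Filter(function(s) s$n_points >= 5 && is.finite(s$arc_length) &&
                   s$arc_length > 0, segs)
  desc <- lapply(segs, segment_descriptors,
                 curvature_peak_threshold = config$curvature_peak_threshold)
  fv <- extract_features(desc)
  if (return_intermediate)
    list(features = fv, vesselness = vmap, mask = mask, segments = segs)
  else fv
}
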