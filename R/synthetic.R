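#' Parameters of the synthetic CE-NBI vessel renderer
#'
#' The generator emulates the two vascular-change regimes seen in CE-NBI
#' frames as 2-D projections: longitudinal changes (LVC) as elongated,
#' low-curvature dark curves, and perpendicular changes (PVC) as hooked,
#' looping, high-curvature curves. The two curvature scales are separated by
#' construction (`lvc_kappa_max < min(pvc_kappa_range)`) so that the
#' curvature features carry the class signal.
#'
#' @param regime `"LVC"` (benign-like, label 0) or `"PVC"` (malignant-like,
#'   label 1).
#' @param n_vessels Vessels rendered per image.
#' @param shape Image shape `c(rows, cols)`. Default `c(256, 320)`, a
#'   quarter-linear-scale version of the 1008 x 1280 clinical frames;
#'   full-size rendering is available by passing `c(1008, 1280)`.
#' @param width_range Range of the vessel tube's Gaussian cross-profile
#'   sigma (pixels).
#' @param lvc_kappa_max Maximum ground-truth curvature of LVC paths (1/px).
#' @param pvc_kappa_range Curvature range of the high-curvature bouts of PVC
#'   paths (1/px).
#' @param background Mean background (mucosa) intensity in `[0, 1]`.
#' @param texture_amp Amplitude of the smooth background texture.
#' @param texture_scale Correlation length of the background texture (px).
#'   Fixed by the endoscope magnification, not by the crop size; the default
#'   16 px corresponds to the quarter-scale rendering of the default shape.
#' @param vessel_depth Intensity drop at a vessel centerline.
#' @param blur_sigma Gaussian blur applied to the rendered image (px).
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed (mandatory for the cohort generator).
#' @return A list of class `vessel_sim_params`.
#' @export
vessel_sim_params <- function(regime = c("LVC", "PVC"),
                              n_vessels = 4,
                              shape = c(256, 320),
                              width_range = c(0.8, 1.8),
                              lvc_kappa_max = 0.02,
                              pvc_kappa_range = c(0.15, 0.30),
                              background = 0.85,
                              texture_amp = 0.02,
                              texture_scale = 16,
                              vessel_depth = 0.45,
                              blur_sigma = 0.8,
                              noise_sd = 0.01,
                              seed = NULL) {
  regime <- match.arg(regime)
  if (length(shape) != 2 || any(shape < 64))
    stop("`shape` must be two dims, each >= 64")
  if (lvc_kappa_max <= 0 || any(pvc_kappa_range <= 0))
    stop("curvature scales must be positive")
  if (diff(pvc_kappa_range) < 0) stop("`pvc_kappa_range` must be increasing")
  structure(list(
    regime = regime, n_vessels = as.integer(n_vessels),
    shape = as.integer(shape), width_range = width_range,
    lvc_kappa_max = lvc_kappa_max, pvc_kappa_range = pvc_kappa_range,
    background = background, texture_amp = texture_amp,
    texture_scale = texture_scale,
    vessel_depth = vessel_depth, blur_sigma = blur_sigma,
    noise_sd = noise_sd, seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "vessel_sim_params")
}

# one curvature sequence for a path of the given regime
sim_kappa <- function(params, len) {
  if (params$regime == "LVC") {
    s <- seq_len(len)
    lambda <- stats::runif(2, 0.5, 1.5) * len
    phi <- stats::runif(2, 0, 2 * pi)
    k <- sin(2 * pi * s / lambda[1] + phi[1]) +
      0.5 * sin(2 * pi * s / lambda[2] + phi[2])
    mk <- max(abs(k))
    if (mk < 1e-9) return(rep(0, len))
    k / mk * params$lvc_kappa_max * stats::runif(1, 0.4, 1)
  } else {
    # alternate low/high-curvature bouts; start and end with a high bout so
    # the high-curvature fraction of arc length stays above 0.3 even for
    # short paths
    k <- numeric(0)
    high <- TRUE
    while (length(k) < len || high) {
      if (high) {
        bl <- sample(12:22, 1)
        k <- c(k, rep(sample(c(-1, 1), 1) *
                        stats::runif(1, params$pvc_kappa_range[1],
                                     params$pvc_kappa_range[2]), bl))
      } else {
        bl <- sample(5:15, 1)
        k <- c(k, rep(stats::runif(1, -0.02, 0.02), bl))
      }
      high <- !high
    }
    k
  }
}

#' Draw one ground-truth vessel centerline
#'
#' Integrates a regime-specific curvature sequence into a planar path with
#' unit (1 px) steps, starting at a random interior point with a random
#' heading, truncated at the image margin. Uses the current RNG state.
#'
#' @param params A [vessel_sim_params()].
#' @return A list: `points` (n x 2 matrix of (row, col)), `width` (tube
#'   sigma, px), `kappa` (ground-truth signed curvature per point, 1/px).
#' @export
draw_vessel_path <- function(params) {
  nr <- params$shape[1]; nc <- params$shape[2]
  margin <- 10
  best <- NULL
  for (attempt in 1:30) {
    len <- round(stats::runif(1, 0.45, 0.8) * min(nr, nc))
    kap <- sim_kappa(params, len)
    len <- length(kap)
    theta <- stats::runif(1, 0, 2 * pi) + cumsum(c(0, kap[-len]))
    r0 <- stats::runif(1, margin + 0.2 * nr, nr - margin - 0.2 * nr)
    c0 <- stats::runif(1, margin + 0.2 * nc, nc - margin - 0.2 * nc)
    r <- r0 + cumsum(c(0, sin(theta[-len])))
    cc <- c0 + cumsum(c(0, cos(theta[-len])))
    inside <- r > margin & r < nr - margin & cc > margin & cc < nc - margin
    cut <- if (all(inside)) len else which(!inside)[1L] - 1L
    if (cut < 30) next
    pts <- cbind(row = r[1:cut], col = cc[1:cut])
    kap <- kap[1:cut]
    if (params$regime == "PVC" && mean(abs(kap) >= 0.1) < 0.3) next
    cand <- list(points = pts,
                 width = stats::runif(1, params$width_range[1],
                                      params$width_range[2]),
                 kappa = kap)
    if (is.null(best) || nrow(cand$points) > nrow(best$points)) best <- cand
    if (nrow(cand$points) >= 0.6 * len) break
  }
  if (is.null(best)) stop("failed to draw a vessel path inside the image")
  best
}

#' Render vessel paths into a CE-NBI-like grayscale image
#'
#' Vessels are stamped as dark tubes with a Gaussian cross-profile on a
#' bright, smoothly textured mucosa-like background; the image is then
#' blurred and corrupted with additive Gaussian noise, and clamped to
#' `[0, 1]`. Uses the current RNG state (texture and noise).
#'
#' @param paths List of paths from [draw_vessel_path()].
#' @param params A [vessel_sim_params()].
#' @return A list: `image` (matrix in `[0, 1]`), `mask` (logical ground-truth
#'   tube support), `paths` (the input paths).
#' @export
render_image <- function(paths, params) {
  if (!length(paths)) stop("need at least one vessel path")
  nr <- params$shape[1]; nc <- params$shape[2]
  tex <- matrix(stats::rnorm(nr * nc), nr, nc)
  # brush must fit inside the image for small test renders
  tex_sigma <- min(params$texture_scale, (min(nr, nc) - 3) / 6)
  tex <- EBImage::gblur(tex, sigma = tex_sigma)
  tex <- (tex - mean(tex)) / max(stats::sd(tex), 1e-12)
  img <- params$background + params$texture_amp * tex
  mask <- matrix(FALSE, nr, nc)
  for (p in paths) {
    ri <- pmin(pmax(round(p$points[, 1]), 1), nr)
    ci <- pmin(pmax(round(p$points[, 2]), 1), nc)
    m0 <- matrix(1, nr, nc)
    m0[cbind(ri, ci)] <- 0
    d <- EBImage::distmap(m0)
    img <- img - params$vessel_depth * exp(-d^2 / (2 * p$width^2))
    mask <- mask | (d <= 2 * p$width)
  }
  # sensor noise enters before the final optical/compression low-pass, so
  # the rendered noise is spatially correlated as in real still frames
  if (params$noise_sd > 0) img <- img + stats::rnorm(nr * nc, 0, params$noise_sd)
  if (params$blur_sigma > 0) img <- EBImage::gblur(img, sigma = params$blur_sigma)
  list(image = pmin(pmax(img, 0), 1), mask = mask, paths = paths)
}

#' Generate a patient-structured synthetic cohort
#'
#' Each synthetic patient is assigned one regime (LVC, label 0, with a
#' benign histopathology name; PVC, label 1, with a malignant one) and a
#' per-patient appearance jitter — vessel width multiplier, background
#' shift, noise multiplier — shared across that patient's images, emulating
#' the within-patient correlation of consecutive endoscopic frames. The
#' curvature scales are never jittered per patient, so the class signal
#' rides exclusively on the regime. Images are written as lossless PNG when
#' `out_dir` is given, otherwise kept in memory.
#'
#' @param n_patients Number of patients (>= 2; both classes represented).
#' @param images_per_patient Range `c(min, max)` of images per patient.
#' @param balance Fraction of LVC (benign) patients.
#' @param params_lvc,params_pvc [vessel_sim_params()] for the two regimes.
#' @param out_dir Output directory for PNGs and `manifest.csv`, or `NULL`
#'   to keep images in memory.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of it.
#' @return A list of class `cenbi_cohort`: `manifest` (a `cenbi_manifest`),
#'   `images` (named list of matrices, or `NULL` when written to disk),
#'   `ground_truth` (named list of per-image path lists), `out_dir`.
#' @export
generate_cohort <- function(n_patients = 40,
                            images_per_patient = c(10, 10),
                            balance = 0.5,
                            params_lvc = vessel_sim_params("LVC"),
                            params_pvc = vessel_sim_params("PVC"),
                            out_dir = NULL,
                            seed = 1L) {
  if (n_patients < 2) stop("need at least 2 patients")
  n_lvc <- round(balance * n_patients)
  if (n_lvc < 1 || n_lvc > n_patients - 1)
    stop("`balance` must leave at least one patient per class")
  if (params_lvc$lvc_kappa_max >= params_pvc$pvc_kappa_range[1])
    warning("curvature scales are not separated (LVC max >= PVC min): ",
            "the regimes are statistically indistinguishable")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  tab <- histopathology_table()
  benign_names <- tab$histopathology[tab$lesion_type == "benign"]
  malignant_names <- tab$histopathology[tab$lesion_type == "malignant"]
  set.seed(as.integer(seed))
  rows <- list(); images <- list(); gt <- list()
  for (i in seq_len(n_patients)) {
    is_lvc <- i <= n_lvc
    params <- if (is_lvc) params_lvc else params_pvc
    pid <- sprintf("sp%03d", i)
    histo <- if (is_lvc) benign_names[(i - 1L) %% length(benign_names) + 1L]
    else malignant_names[(i - n_lvc - 1L) %% length(malignant_names) + 1L]
    n_img <- if (images_per_patient[1] == images_per_patient[2])
      images_per_patient[1] else
        sample(images_per_patient[1]:images_per_patient[2], 1)
    # appearance jitter shared across the patient's frames
    width_mult <- stats::runif(1, 0.85, 1.15)
    bg_shift <- stats::runif(1, -0.04, 0.04)
    noise_mult <- stats::runif(1, 0.8, 1.2)
    pp <- params
    pp$width_range <- params$width_range * width_mult
    pp$background <- params$background + bg_shift
    pp$noise_sd <- params$noise_sd * noise_mult
    for (j in seq_len(n_img)) {
      iid <- sprintf("%s_i%02d", pid, j)
      paths <- lapply(seq_len(pp$n_vessels), function(k) draw_vessel_path(pp))
      rend <- render_image(paths, pp)
      fp <- sprintf("%s.png", iid)
      if (!is.null(out_dir)) {
        write_image_gray(rend$image, file.path(out_dir, fp))
      } else {
        images[[iid]] <- rend$image
      }
      gt[[iid]] <- rend$paths
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = iid, patient_id = pid, filepath = fp,
        histopathology = histo,
        lesion_type = if (is_lvc) "benign" else "malignant",
        label = if (is_lvc) 0L else 1L, subset = "unassigned",
        stringsAsFactors = FALSE)
    }
  }
  manifest <- validate_manifest(do.call(rbind, rows))
  if (!is.null(out_dir))
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  structure(list(manifest = manifest,
                 images = if (is.null(out_dir)) images else NULL,
                 ground_truth = gt, out_dir = out_dir),
            class = "cenbi_cohort")
}

#' Equalize the curvature scales of a regime-parameter pair
#'
#' Returns PVC parameters whose curvature construction is copied from the
#' given generator but whose high-curvature bouts are disabled by drawing
#' LVC-style paths, i.e. both regimes sample the same curvature
#' distribution. Used to verify that the classifiers have no signal beyond
#' vessel geometry (leakage guard).
#'
#' @param params_lvc The LVC parameters to copy the curvature law from.
#' @param params_pvc The PVC parameters whose appearance settings are kept.
#' @return A `vessel_sim_params` that renders like PVC but curves like LVC.
#' @export
equalize_curvature <- function(params_lvc, params_pvc) {
  out <- params_pvc
  out$regime <- "LVC"
  out$lvc_kappa_max <- params_lvc$lvc_kappa_max
  out
}
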