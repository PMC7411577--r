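# Independent oracles and fixture builders used across the suite.
# The oracles deliberately avoid the package's convolution/tracing code
# paths: dense direct convolution, plain finite differences, and analytic
# parametric curves.

# wrap a point matrix as a resampled segment (uniform spacing assumed)
as_segment <- function(pts, spacing = 1) {
  pts <- cbind(row = pts[, 1], col = pts[, 2])
  steps <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  structure(list(points = pts, arc_length = sum(steps), n_points = nrow(pts),
                 spacing = spacing, smoothed = TRUE),
            class = "vessel_segment")
}

# circle arc of radius r, arc-length spacing ds, spanning `angle` radians
circle_segment <- function(r, ds = 1, angle = 2 * pi * 0.9, center = c(0, 0),
                           phase = 0) {
  s <- seq(0, r * angle, by = ds)
  a <- phase + s / r
  as_segment(cbind(center[1] + r * sin(a), center[2] + r * cos(a)),
             spacing = ds)
}

line_segment <- function(n = 50, ds = 1, angle = 0, origin = c(0, 0)) {
  s <- seq(0, (n - 1) * ds, by = ds)
  as_segment(cbind(origin[1] + s * sin(angle), origin[2] + s * cos(angle)),
             spacing = ds)
}

# brute-force scale-space Hessian: dense Gaussian smoothing (direct O(k^2)
# convolution, symmetric padding) followed by [1,-2,1]/cross finite
# differences, gamma-normalized by sigma^2. Interior pixels only (NA rim).
oracle_hessian_fd <- function(img, sigma) {
  n_r <- nrow(img); n_c <- ncol(img)
  h <- ceiling(5 * sigma)
  x <- seq(-h, h)
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  K <- outer(g, g)
  ri <- c(rev(seq_len(h + 1)), seq_len(n_r), n_r - seq_len(h + 1) + 1)
  ci <- c(rev(seq_len(h + 1)), seq_len(n_c), n_c - seq_len(h + 1) + 1)
  P <- img[ri, ci]
  sm <- matrix(NA_real_, n_r, n_c)
  for (r in seq_len(n_r)) for (cc in seq_len(n_c))
    sm[r, cc] <- sum(K * P[r:(r + 2 * h) + 1, cc:(cc + 2 * h) + 1])
  Hrr <- Hcc <- Hrc <- matrix(NA_real_, n_r, n_c)
  for (r in 2:(n_r - 1)) for (cc in 2:(n_c - 1)) {
    Hrr[r, cc] <- sm[r + 1, cc] - 2 * sm[r, cc] + sm[r - 1, cc]
    Hcc[r, cc] <- sm[r, cc + 1] - 2 * sm[r, cc] + sm[r, cc - 1]
    Hrc[r, cc] <- (sm[r + 1, cc + 1] - sm[r + 1, cc - 1] -
                     sm[r - 1, cc + 1] + sm[r - 1, cc - 1]) / 4
  }
  disc <- sqrt(((Hrr - Hcc) / 2)^2 + Hrc^2)
  list(low = sigma^2 * ((Hrr + Hcc) / 2 - disc),
       high = sigma^2 * ((Hrr + Hcc) / 2 + disc))
}

# scalar reference of the tubularity response function
oracle_jerman_response <- function(x, lrho) {
  if (is.na(x) || x <= 0 || lrho <= 0) return(0)
  if (x >= lrho / 2) return(1)
  min(1, x^2 * (lrho - x) * (3 / (x + lrho))^3)
}

# image with a dark horizontal line of Gaussian cross-profile
dark_line_image <- function(n = 64, width = 2, depth = 0.5, row0 = n / 2) {
  outer(seq_len(n), seq_len(n), function(r, c)
    1 - depth * exp(-(r - row0)^2 / (2 * width^2)))
}

# dense numerical-integration oracle for the six descriptors of a
# parametric curve (row(t), col(t)) on [t0, t1]
oracle_curve_descriptors <- function(frow, fcol, t0, t1, dt = 1e-3,
                                     peak_threshold = 0.15) {
  t <- seq(t0, t1, by = dt)
  r <- frow(t); cc <- fcol(t)
  dr <- diff(r) / dt; dc <- diff(cc) / dt
  tm <- (t[-1] + t[-length(t)]) / 2
  sp <- sqrt(dr^2 + dc^2)
  ds <- sp * dt
  L <- sum(ds)
  theta <- atan2(dr, dc)
  R <- Mod(sum(exp(2i * theta) * ds) / L)
  # curvature from second differences of the parametric curve
  d2r <- diff(r, differences = 2) / dt^2
  d2c <- diff(cc, differences = 2) / dt^2
  dr_m <- (dr[-1] + dr[-length(dr)]) / 2
  dc_m <- (dc[-1] + dc[-length(dc)]) / 2
  kap <- (dc_m * d2r - dr_m * d2c) / (dr_m^2 + dc_m^2)^1.5
  ds_m <- (ds[-1] + ds[-length(ds)]) / 2
  Lm <- sum(ds_m)
  ak <- abs(kap)
  n <- length(ak)
  pk <- sum(ak[2:(n - 1)] > ak[1:(n - 2)] & ak[2:(n - 1)] >= ak[3:n] &
              ak[2:(n - 1)] > peak_threshold)
  sg <- sign(kap); sg <- sg[sg != 0]
  chord <- sqrt((r[length(r)] - r[1])^2 + (cc[length(cc)] - cc[1])^2)
  list(dir_var = 1 - R,
       turn_rate = sum(ak * ds_m) / Lm,
       curv_mean = sum(ak * ds_m) / Lm,
       peak_count = pk,
       tortuosity = L / chord,
       inflect_count = sum(diff(sg) != 0),
       arc_length = L)
}

# render a single-regime image deterministically
render_one <- function(regime, seed, shape = c(160, 200), n_vessels = 3, ...) {
  set.seed(seed)
  p <- vessel_sim_params(regime, shape = shape, n_vessels = n_vessels, ...)
  paths <- lapply(seq_len(n_vessels), function(i) draw_vessel_path(p))
  render_image(paths, p)
}
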