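#' Specification of the synthetic thermal/PET phantom
#'
#' Defines the study conditions the generator emulates: a torso silhouette
#' imaged at 5-s intervals across an acclimatization period, a 10-min
#' initial cooling period and a final period; a warm supraclavicular blob
#' per side whose amplitude rises as a saturating exponential after cooling
#' onset (cold session) or stays at baseline (vehicle session); a cooler
#' sternal reference area; Gaussian sensor noise; a paired PET volume with
#' uptake blobs colocalized (through a known degree-2 warp) with the warm
#' patches; and quasi-uniform control-point pairs. All randomness derives
#' from `seed`; identical specs produce byte-identical outputs.
#'
#' @param dims Thermal frame dimensions `c(nrow, ncol)`.
#' @param interval_s Frame interval (s).
#' @param acclim_s,initial_s,final_s Period durations (s). Cooling onset is
#'   the end of acclimatization.
#' @param background_c,skin_c Background and skin temperature (degC).
#' @param cx Body midline column.
#' @param neck_top,shoulder_y Row of the neck top and of the shoulder line.
#' @param neck_halfwidth,neck_slope Neck half-width at the top (px) and its
#'   widening per row toward the shoulders.
#' @param torso_halfwidth Torso half-width (px).
#' @param head_rx,head_ry Head ellipse radii (px).
#' @param blob_offset Supraclavicular blob center offset `c(dx, dy)` from
#'   the sternal apex: centers at `(cx -/+ dx, sternal_y - dy)`.
#' @param blob_sigma_px Spatial standard deviation of the warm blob (px).
#' @param baseline_amp_c Baseline blob amplitude above skin (degC).
#' @param delta_t_max_c Plateau activation amplitude (degC, cold session).
#' @param tau_s Activation time constant (s).
#' @param onset_s Cooling onset (s), default end of acclimatization.
#' @param noise_sd_c Per-pixel sensor noise SD (degC).
#' @param calibration [calibration_constants()] used to encode frames.
#' @param pet_dims,pet_spacing_mm PET volume grid and voxel spacing.
#' @param pet_background,pet_noise_sd Background uptake and voxel noise SD
#'   (phantom units).
#' @param pet_sigma_vox Uptake blob SDs per axis (voxels).
#' @param pet_z_center Slice index of the uptake blob center.
#' @param pet_coupling Uptake amplitude per degC of `delta_t_max_c`.
#' @param pet_vehicle_frac Vehicle-session uptake amplitude as a fraction
#'   of the cold-session amplitude.
#' @param warp_max_shift_px,warp_max_rot_deg,warp_scale_jitter,warp_quad_coef
#'   Ranges of the true thermal-to-projection warp: translation, rotation,
#'   scale deviation, and centered quadratic coefficient magnitude.
#' @param n_control_points Number of control-point pairs (default 70).
#' @param cp_jitter_px Per-axis Gaussian jitter of the fixed-frame control
#'   points (px).
#' @param seed RNG seed; all generator randomness derives from it.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(96L, 128L), interval_s = 5,
                         acclim_s = 60, initial_s = 600, final_s = 60,
                         background_c = 22, skin_c = 34,
                         cx = 64, neck_top = 20, shoulder_y = 48,
                         neck_halfwidth = 10, neck_slope = 0.15,
                         torso_halfwidth = 45, head_rx = 13, head_ry = 10,
                         blob_offset = c(8, 16), blob_sigma_px = 6,
                         baseline_amp_c = 2, delta_t_max_c = 0.4,
                         tau_s = 120, onset_s = acclim_s,
                         noise_sd_c = 0.05,
                         calibration = calibration_constants(),
                         pet_dims = c(96L, 128L, 16L),
                         pet_spacing_mm = c(2, 2, 3),
                         pet_background = 1, pet_noise_sd = 0.15,
                         pet_sigma_vox = c(5, 5, 3), pet_z_center = 8,
                         pet_coupling = 20, pet_vehicle_frac = 0.01,
                         warp_max_shift_px = 3, warp_max_rot_deg = 2,
                         warp_scale_jitter = 0.02, warp_quad_coef = 1e-4,
                         n_control_points = 70L, cp_jitter_px = 0.5,
                         seed = 1L) {
  spec <- as.list(environment())
  if (any(c(acclim_s, initial_s, final_s, interval_s) <= 0)) {
    stop("period durations and frame interval must be positive")
  }
  if (blob_sigma_px < 0 || noise_sd_c < 0 || pet_noise_sd < 0 ||
      cp_jitter_px < 0) {
    stop("standard deviations must be non-negative")
  }
  structure(spec, class = "phantom_spec")
}

sternal_point <- function(spec) c(spec$cx, spec$shoulder_y + 12)

blob_centers <- function(spec) {
  st <- sternal_point(spec)
  rbind(left = c(spec$cx - spec$blob_offset[1], st[2] - spec$blob_offset[2]),
        right = c(spec$cx + spec$blob_offset[1], st[2] - spec$blob_offset[2]))
}

# Logical skin silhouette: torso slab, widening neck, head ellipse.
phantom_silhouette <- function(spec) {
  nr <- spec$dims[1]; nc <- spec$dims[2]
  X <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  Y <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  torso <- Y >= spec$shoulder_y & abs(X - spec$cx) <= spec$torso_halfwidth
  neck <- Y >= spec$neck_top & Y < spec$shoulder_y &
    abs(X - spec$cx) <= spec$neck_halfwidth +
    spec$neck_slope * (Y - spec$neck_top)
  head_cy <- spec$neck_top - spec$head_ry
  head <- ((X - spec$cx) / spec$head_rx)^2 +
    ((Y - head_cy) / spec$head_ry)^2 <= 1
  torso | neck | head
}

#' Apices implied by the phantom geometry
#'
#' @param spec A [phantom_spec()].
#' @return An [apex_set()].
#' @export
phantom_apices <- function(spec) {
  nh <- spec$neck_halfwidth
  drop_w <- nh + spec$neck_slope * (spec$shoulder_y - spec$neck_top)
  apex_set(
    superolateral_left = c(spec$cx - nh, spec$neck_top),
    superolateral_right = c(spec$cx + nh, spec$neck_top),
    acromioclavicular_left = c(spec$cx - drop_w, spec$shoulder_y),
    acromioclavicular_right = c(spec$cx + drop_w, spec$shoulder_y),
    sternal = sternal_point(spec),
    dims = spec$dims)
}

# True (sub-pixel) neck edge path for one side.
phantom_true_edge <- function(spec, side = c("left", "right")) {
  side <- match.arg(side)
  y <- seq(spec$neck_top, spec$shoulder_y)
  half <- spec$neck_halfwidth + spec$neck_slope * (y - spec$neck_top)
  x <- if (side == "left") spec$cx - half else spec$cx + half
  data.frame(x = x, y = y)
}

# Draw the true degree-2 thermal->projection warp for a spec; returns
# 6 x 2 coefficient matrix over the basis (1, x, y, x^2, xy, y^2).
draw_true_warp <- function(spec) {
  tx <- stats::runif(2, -spec$warp_max_shift_px, spec$warp_max_shift_px)
  th <- stats::runif(1, -spec$warp_max_rot_deg, spec$warp_max_rot_deg) *
    pi / 180
  s <- 1 + stats::runif(1, -spec$warp_scale_jitter, spec$warp_scale_jitter)
  q <- stats::runif(6, -spec$warp_quad_coef, spec$warp_quad_coef)
  c0 <- c(spec$cx, spec$shoulder_y)
  warp_fun <- function(p) {
    u <- p[, 1] - c0[1]; v <- p[, 2] - c0[2]
    cbind(c0[1] + tx[1] + s * (cos(th) * u - sin(th) * v) +
            q[1] * u^2 + q[2] * u * v + q[3] * v^2,
          c0[2] + tx[2] + s * (sin(th) * u + cos(th) * v) +
            q[4] * u^2 + q[5] * u * v + q[6] * v^2)
  }
  # the map is exactly degree 2: recover its global coefficients exactly
  px <- cbind(rep(c(10, 40, 70, 100), 3),
              rep(c(10, 48, 90), each = 4))
  X <- quad_design(px[, 1], px[, 2])
  qr.coef(qr(X), warp_fun(px))
}

#' Evaluate the phantom's true warp at points
#'
#' @param truth A ground-truth object from the generators.
#' @param points n-by-2 matrix of thermal-frame `c(x, y)` points.
#' @return n-by-2 matrix in projection coordinates.
#' @export
true_warp_points <- function(truth, points) {
  points <- matrix(as.numeric(as.matrix(points)), ncol = 2L)
  quad_design(points[, 1], points[, 2]) %*% truth$warp_coef
}

#' Ground truth implied by a phantom specification
#'
#' Everything needed to score recovery tests without rerunning the
#' pipeline: apices, sub-pixel neck edges, blob centers in both frames, the
#' true degree-2 warp coefficients, the activation curve and the analytic
#' outcome values (base/peak/delta of the moving-average-smoothed noise-free
#' activation curve).
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_truth`.
#' @export
phantom_truth <- function(spec) {
  set.seed(spec$seed)
  warp_coef <- draw_true_warp(spec)
  centers_ti <- blob_centers(spec)
  truth <- list(spec_seed = spec$seed,
                apices = phantom_apices(spec),
                edge_left = phantom_true_edge(spec, "left"),
                edge_right = phantom_true_edge(spec, "right"),
                blob_centers_ti = centers_ti,
                warp_coef = warp_coef)
  truth$blob_centers_mip <- true_warp_points(truth, centers_ti)
  truth$activation <- function(t, session = "cold") {
    a <- rep(spec$baseline_amp_c, length(t))
    if (session == "cold") {
      on <- t >= spec$onset_s
      a[on] <- a[on] + spec$delta_t_max_c *
        (1 - exp(-(t[on] - spec$onset_s) / spec$tau_s))
    }
    a
  }
  truth$outcomes_true <- analytic_outcomes(spec)
  structure(truth, class = "phantom_truth")
}

frame_times <- function(spec) {
  total <- spec$acclim_s + spec$initial_s + spec$final_s
  seq(0, total - spec$interval_s, by = spec$interval_s)
}

frame_periods <- function(spec, t = frame_times(spec)) {
  ifelse(t < spec$acclim_s, "acclimatization",
         ifelse(t < spec$acclim_s + spec$initial_s, "initial", "final"))
}

# Analytic base/peak/delta of the smoothed activation curve: the
# noise-free amplitude A(t) sampled at the frame times, smoothed with the
# same moving average the pipeline applies, and reduced with the same
# half-open windows.
analytic_outcomes <- function(spec, session = "cold", period = 5L) {
  t <- frame_times(spec)
  a <- rep(spec$baseline_amp_c, length(t))
  if (session == "cold") {
    on <- t >= spec$onset_s
    a[on] <- a[on] + spec$delta_t_max_c *
      (1 - exp(-(t[on] - spec$onset_s) / spec$tau_s))
  }
  sm <- smooth_series(temperature_series(t, a), period = period)
  initial <- compute_outcomes(sm, spec$onset_s, peak_window_s = spec$initial_s)
  combined <- compute_outcomes(sm, spec$onset_s, peak_window_s = Inf)
  list(base = initial$base, peak_initial = initial$peak,
       delta10 = initial$delta, peak_combined = combined$peak,
       delta_combined = combined$delta)
}

#' Generate a synthetic thermal frame sequence
#'
#' Per frame, the temperature field is background + silhouette x (skin -
#' background) + the two supraclavicular Gaussian blobs at amplitude
#' `A(t)` + i.i.d. Gaussian sensor noise. `A(t)` is the baseline amplitude
#' plus, in the cold session, a saturating-exponential rise after onset.
#' Frames are encoded to integer radiometric counts and decoded back, so
#' the returned temperatures carry the true quantization of the frame
#' format.
#'
#' @param spec A [phantom_spec()].
#' @param session `"cold"` or `"vehicle"`.
#' @param return_counts Also return the raw [radiometric_frame()]s.
#'
#' @return List with `frames` (list of [temperature_frame()]),
#'   `apices`, `periods`, `truth` (a [phantom_truth()]) and optionally
#'   `raw_frames`.
#' @export
generate_thermal_sequence <- function(spec, session = c("cold", "vehicle"),
                                      return_counts = FALSE) {
  session <- match.arg(session)
  truth <- phantom_truth(spec)
  sil <- phantom_silhouette(spec)
  ctr <- blob_centers(spec)
  idx <- round(ctr[, 2:1, drop = FALSE])
  if (!all(sil[idx])) stop("blob center lies outside the silhouette")
  nr <- spec$dims[1]; nc <- spec$dims[2]
  X <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  Y <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  blob_pattern <- exp(-((X - ctr[1, 1])^2 + (Y - ctr[1, 2])^2) /
                        (2 * spec$blob_sigma_px^2)) +
    exp(-((X - ctr[2, 1])^2 + (Y - ctr[2, 2])^2) /
          (2 * spec$blob_sigma_px^2))
  static <- spec$background_c + sil * (spec$skin_c - spec$background_c)
  t <- frame_times(spec)
  amp <- truth$activation(t, session)
  set.seed(spec$seed + if (session == "cold") 1000L else 2000L)
  frames <- vector("list", length(t))
  raw_frames <- if (return_counts) vector("list", length(t)) else NULL
  for (i in seq_along(t)) {
    temp <- static + amp[i] * blob_pattern
    if (spec$noise_sd_c > 0) {
      temp <- temp + matrix(stats::rnorm(nr * nc, sd = spec$noise_sd_c),
                            nr, nc)
    }
    fid <- sprintf("%s_%04d", session, i)
    raw <- temperature_to_counts(
      temperature_frame(temp, t[i], fid), spec$calibration)
    frames[[i]] <- counts_to_temperature(raw)
    if (return_counts) raw_frames[[i]] <- raw
  }
  out <- list(frames = frames, apices = truth$apices,
              periods = frame_periods(spec, t), truth = truth,
              session = session)
  if (return_counts) out$raw_frames <- raw_frames
  out
}

#' Generate a paired synthetic PET/CT volume
#'
#' Uptake blobs are placed where the true warp maps the thermal blob
#' centers, at `pet_z_center` along the projection axis; the cold-session
#' amplitude exceeds the vehicle amplitude by construction. The CT volume
#' is a simple body-density ellipsoid.
#'
#' @param spec A [phantom_spec()].
#' @param session `"cold"` or `"vehicle"`.
#' @param amplitude Uptake blob amplitude; defaults to
#'   `pet_coupling * delta_t_max_c` (cold) scaled by `pet_vehicle_frac`
#'   (vehicle).
#'
#' @return List with `mrgluc` and `ct` ([scalar_volume()]s), `truth` and
#'   `amplitude`.
#' @export
generate_pet_volume <- function(spec, session = c("cold", "vehicle"),
                                amplitude = NULL) {
  session <- match.arg(session)
  truth <- phantom_truth(spec)
  if (is.null(amplitude)) {
    amplitude <- spec$pet_coupling * spec$delta_t_max_c
    if (session == "vehicle") amplitude <- amplitude * spec$pet_vehicle_frac
  }
  d <- spec$pet_dims
  X <- array(rep(seq_len(d[2]), each = d[1]), d)
  Y <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  Z <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  ctr <- truth$blob_centers_mip
  sg <- spec$pet_sigma_vox
  blob <- exp(-((X - ctr[1, 1])^2 / (2 * sg[1]^2) +
                  (Y - ctr[1, 2])^2 / (2 * sg[2]^2) +
                  (Z - spec$pet_z_center)^2 / (2 * sg[3]^2))) +
    exp(-((X - ctr[2, 1])^2 / (2 * sg[1]^2) +
            (Y - ctr[2, 2])^2 / (2 * sg[2]^2) +
            (Z - spec$pet_z_center)^2 / (2 * sg[3]^2)))
  set.seed(spec$seed + if (session == "cold") 3000L else 4000L)
  uptake <- spec$pet_background + amplitude * blob
  if (spec$pet_noise_sd > 0) {
    uptake <- uptake + array(stats::rnorm(prod(d), sd = spec$pet_noise_sd), d)
  }
  body <- ((X - spec$cx) / (d[2] * 0.45))^2 +
    ((Z - spec$pet_z_center) / (d[3] * 0.45))^2 <= 1
  ct <- ifelse(body, 40, -1000)
  list(mrgluc = scalar_volume(uptake, spec$pet_spacing_mm, "MRgluc",
                              paste0("phantom_", session)),
       ct = scalar_volume(ct, spec$pet_spacing_mm, "CT",
                          paste0("phantom_", session, "_ct")),
       truth = truth, amplitude = amplitude, session = session)
}

#' Generate control-point pairs from the true warp
#'
#' Points quasi-uniform over the supraclavicular neighborhood of the
#' thermal frame; fixed-frame positions are the true warp of the moving
#' points plus per-axis Gaussian jitter.
#'
#' @param spec A [phantom_spec()].
#' @param jitter_px Jitter SD (px); defaults to `spec$cp_jitter_px`.
#' @return A [control_point_pairs()] with attribute `truth`.
#' @export
generate_control_points <- function(spec, jitter_px = spec$cp_jitter_px) {
  truth <- phantom_truth(spec)
  n <- spec$n_control_points
  ngx <- max(3L, round(sqrt(n * 10 / 7)))
  ngy <- ceiling(n / ngx)
  gx <- seq(spec$cx - 24, spec$cx + 24, length.out = ngx)
  gy <- seq(spec$neck_top - 2, sternal_point(spec)[2] + 4,
            length.out = ngy)
  moving <- cbind(rep(gx, times = ngy), rep(gy, each = ngx))[seq_len(n), ]
  set.seed(spec$seed + 5000L)
  moving <- moving + matrix(stats::runif(2 * n, -1.5, 1.5), n, 2)
  fixed <- true_warp_points(truth, moving)
  if (jitter_px > 0) {
    fixed <- fixed + matrix(stats::rnorm(2 * n, sd = jitter_px), n, 2)
  }
  pairs <- control_point_pairs(moving, fixed)
  attr(pairs, "truth") <- truth
  pairs
}

#' Generate a synthetic study cohort
#'
#' Per-subject phantom specifications for paired cold and vehicle
#' sessions. The activation plateau and the PET uptake amplitude are drawn
#' jointly — uptake is proportional to the plateau with multiplicative
#' lognormal jitter — so the expected correlation between the thermal and
#' PET readouts is controlled by `effect_size` and the jitter. The
#' regional kinetic uptake estimate (an external input in the real
#' analysis) is emulated the same way with larger jitter.
#'
#' @param n_subjects Number of subjects (default 8).
#' @param effect_size Multiplier on the activation plateau (default 1;
#'   0 gives a null cohort).
#' @param seed Cohort RNG seed.
#' @param base_spec Template [phantom_spec()] shared by all subjects.
#'
#' @return An object of class `phantom_cohort`: list with `subjects` (each
#'   with `id`, `spec`, `delta_t_max`, `pet_amplitude`, `mrgluc_bat`),
#'   `effect_size`, `seed`.
#' @export
generate_cohort <- function(n_subjects = 8L, effect_size = 1,
                            seed = 1L, base_spec = phantom_spec()) {
  set.seed(seed)
  dt <- effect_size * pmax(0.1, stats::rnorm(n_subjects, 0.4, 0.15))
  pet_amp <- base_spec$pet_coupling * dt *
    exp(stats::rnorm(n_subjects, 0, 0.25))
  bat <- 0.8 * base_spec$pet_coupling * dt *
    exp(stats::rnorm(n_subjects, 0, 0.4))
  subj_seeds <- sample.int(.Machine$integer.max %/% 2L, n_subjects)
  subjects <- lapply(seq_len(n_subjects), function(i) {
    spec <- base_spec
    spec$delta_t_max_c <- dt[i]
    spec$seed <- subj_seeds[i]
    list(id = sprintf("S%02d", i), spec = spec, delta_t_max = dt[i],
         pet_amplitude = pet_amp[i],
         pet_amplitude_vehicle = pet_amp[i] * base_spec$pet_vehicle_frac,
         mrgluc_bat = bat[i])
  })
  structure(list(subjects = subjects, effect_size = effect_size,
                 seed = seed, base_spec = base_spec),
            class = "phantom_cohort")
}

#' Synthetic step/slant edge phantom for contour validation
#'
#' A frame with a known (possibly slanted, sub-pixel) lateral skin border:
#' for `side = "left"` the background lies at smaller x and the skin at
#' larger x, matching the left neck border convention. Optionally blurred
#' with a small Gaussian kernel and degraded with sensor noise. The true
#' edge path is returned for scoring.
#'
#' @param seed RNG seed for the noise.
#' @param dims Frame dimensions.
#' @param edge_x Edge column at `y0`.
#' @param slope Edge slant (columns per row).
#' @param y0,y1 Row range of the apices (edge evaluated over it).
#' @param skin_c,background_c Temperatures either side of the edge.
#' @param blur_sigma_px Gaussian blur SD (0 = sharp edge).
#' @param noise_sd_c Sensor noise SD.
#' @param side Border convention: `"left"` = background at smaller x,
#'   `"right"` = background at larger x.
#'
#' @return List with `frame`, `apices`, `true_edge` (data frame `x`, `y`),
#'   `side`.
#' @export
generate_edge_phantom <- function(seed = 1L, dims = c(60L, 80L),
                                  edge_x = 40, slope = 0, y0 = 10, y1 = 40,
                                  skin_c = 34, background_c = 22,
                                  blur_sigma_px = 0, noise_sd_c = 0,
                                  side = c("left", "right")) {
  side <- match.arg(side)
  nr <- dims[1]; nc <- dims[2]
  X <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  Y <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  edge_of <- function(y) edge_x + slope * (y - y0)
  temp <- if (side == "left") {
    ifelse(X >= edge_of(Y), skin_c, background_c)
  } else {
    ifelse(X <= edge_of(Y), skin_c, background_c)
  }
  if (blur_sigma_px > 0) temp <- gaussian_blur(temp, blur_sigma_px)
  set.seed(seed)
  if (noise_sd_c > 0) {
    temp <- temp + matrix(stats::rnorm(nr * nc, sd = noise_sd_c), nr, nc)
  }
  apices <- if (side == "left") {
    apex_set(
      superolateral_left = c(edge_of(y0), y0),
      superolateral_right = c(nc - 2, y0),
      acromioclavicular_left = c(edge_of(y1), y1),
      acromioclavicular_right = c(nc - 1, y1 + 1),
      sternal = c((edge_of(y1) + nc - 1) / 2, min(nr - 1, y1 + 10)),
      dims = dims)
  } else {
    apex_set(
      superolateral_left = c(3, y0),
      superolateral_right = c(edge_of(y0), y0),
      acromioclavicular_left = c(2, y1 + 1),
      acromioclavicular_right = c(edge_of(y1), y1),
      sternal = c((edge_of(y1) + 3) / 2, min(nr - 1, y1 + 10)),
      dims = dims)
  }
  list(frame = temperature_frame(temp, 0, "edge_phantom"),
       apices = apices,
       true_edge = data.frame(x = edge_of(y0:y1), y = y0:y1),
       side = side)
}

# Separable Gaussian blur with replicate padding.
gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(m) { # along rows (vertical)
    padded <- rbind(m[rep(1L, r), , drop = FALSE], m,
                    m[rep(nrow(m), r), , drop = FALSE])
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[j:(j + nrow(m) - 1L), , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(img))))
}

#' Smooth textured phantom for registration validation
#'
#' A smooth random temperature field (bilinearly upsampled coarse Gaussian
#' noise) providing texture for intensity-based registration.
#'
#' @param seed RNG seed.
#' @param dims Frame dimensions.
#' @param coarse Coarse grid dimensions.
#' @param amplitude_c Texture amplitude (degC).
#' @param base_c Mean temperature (degC).
#' @return A [temperature_frame()].
#' @export
generate_texture_phantom <- function(seed = 1L, dims = c(96L, 128L),
                                     coarse = c(12L, 16L),
                                     amplitude_c = 3, base_c = 32) {
  set.seed(seed)
  g <- matrix(stats::rnorm(prod(coarse)), coarse[1], coarse[2])
  sx <- (seq_len(dims[2]) - 1) / (dims[2] - 1) * (coarse[2] - 1) + 1
  sy <- (seq_len(dims[1]) - 1) / (dims[1] - 1) * (coarse[1] - 1) + 1
  sx <- pmin(sx, coarse[2] - 1e-9)
  sy <- pmin(sy, coarse[1] - 1e-9)
  gx <- rep(sx, each = dims[1])
  gy <- rep(sy, times = dims[2])
  fine <- matrix(bilinear_sample(g, gx, gy), dims[1], dims[2])
  temperature_frame(base_c + amplitude_c * fine, 0, "texture_phantom")
}
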