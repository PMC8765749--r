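# Spatial helpers and the per-trial forward model of the widefield camera.
#
# A rendered trial stack is
#   I[y,x,t] = T_v( B * (1 + G1*r1(t) + G2*r2(t) + d(t)) + B*M*h(t) ) + noise
# where B is the baseline fluorescence map, G1/G2 the two Gaussian
# expression-site profiles, r1/r2 the site response time courses (dF/F),
# d(t) a linear drift, M a smooth vascular-like map carrying the heartbeat
# modulation h(t), and T_v a whole-frame subpixel translation by the
# micro-motion vector v_t. Every stochastic component is returned in a
# ground-truth sidecar so each preprocessing stage has an exact oracle.

#' Gaussian spatial profile
#'
#' Unit-peak 2-D isotropic Gaussian parameterized by its full width at
#' half maximum, on a `ny x nx` pixel grid (x right, y down, 1-based).
#'
#' @param ny,nx image size in pixels.
#' @param center `c(x, y)` center in pixels.
#' @param fwhm_px full width at half maximum in pixels (> 0).
#' @return `ny x nx` matrix.
#' @export
gaussian_site_map <- function(ny, nx, center, fwhm_px) {
  stopifnot(fwhm_px > 0, ny >= 1, nx >= 1)
  xs <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  ys <- matrix(seq_len(ny), ny, nx)
  k <- 4 * log(2) / fwhm_px^2
  exp(-k * ((xs - center[1])^2 + (ys - center[2])^2))
}

# Smooth zero-mean unit-sd random map: white noise low-passed with a
# Gaussian transfer function in the Fourier domain (periodic boundary).
# Draws from the current RNG stream.
smooth_random_map <- function(ny, nx, sigma_px = 6) {
  w <- matrix(stats::rnorm(ny * nx), ny, nx)
  fy <- c(0:floor(ny / 2), -(ceiling(ny / 2) - 1):-1) / ny
  fx <- c(0:floor(nx / 2), -(ceiling(nx / 2) - 1):-1) / nx
  h <- exp(-2 * pi^2 * sigma_px^2 *
             (outer(fy^2, rep(1, nx)) + outer(rep(1, ny), fx^2)))
  m <- Re(stats::fft(stats::fft(w) * h, inverse = TRUE)) / (ny * nx)
  (m - mean(m)) / stats::sd(m)
}

#' Translate an image by a subpixel offset
#'
#' Whole-frame translation by `(vx, vy)` pixels using separable
#' Catmull-Rom cubic convolution with clamped edges:
#' `out(x, y) = img(x - vx, y - vy)`. Exact for affine (planar-ramp)
#' images away from the border, which gives the stabilization stage an
#' analytic oracle.
#'
#' @param img matrix (y rows, x columns).
#' @param vx,vy translation in pixels (positive moves content right/down).
#' @return translated matrix of the same size.
#' @export
translate_frame <- function(img, vx, vy) {
  if (vx == 0 && vy == 0) return(img)
  img <- shift_axis(img, vx, along = "x")
  shift_axis(img, vy, along = "y")
}

# 1-D Catmull-Rom shift along rows (x) or columns (y); same fractional
# weights for the whole frame so the interpolation is 4 vectorized taps.
shift_axis <- function(img, v, along = c("x", "y")) {
  along <- match.arg(along)
  if (v == 0) return(img)
  n <- if (along == "x") ncol(img) else nrow(img)
  p <- seq_len(n) - v
  i0 <- floor(p)
  f <- p - i0
  # Catmull-Rom weights for taps at i0-1, i0, i0+1, i0+2
  w1 <- ((-0.5 * f + 1) * f - 0.5) * f
  w2 <- (1.5 * f - 2.5) * f * f + 1
  w3 <- ((-1.5 * f + 2) * f + 0.5) * f
  w4 <- (0.5 * f - 0.5) * f * f
  cl <- function(i) pmin(pmax(i, 1L), n)
  if (along == "x") {
    out <- img[, cl(i0 - 1), drop = FALSE] *
      matrix(w1, nrow(img), n, byrow = TRUE) +
      img[, cl(i0), drop = FALSE] * matrix(w2, nrow(img), n, byrow = TRUE) +
      img[, cl(i0 + 1), drop = FALSE] * matrix(w3, nrow(img), n, byrow = TRUE) +
      img[, cl(i0 + 2), drop = FALSE] * matrix(w4, nrow(img), n, byrow = TRUE)
  } else {
    out <- img[cl(i0 - 1), , drop = FALSE] * w1 +
      img[cl(i0), , drop = FALSE] * w2 +
      img[cl(i0 + 1), , drop = FALSE] * w3 +
      img[cl(i0 + 2), , drop = FALSE] * w4
  }
  out
}

# GCaMP-like response kernel: exponential rise from `onset_ms` while the
# stimulus is on, slow exponential decay after `offset_ms` (the indicator
# outlives the stimulus). Unit asymptote.
response_kernel <- function(t_ms, onset_ms, offset_ms,
                            tau_rise_ms = 60, tau_decay_ms = 800) {
  k <- numeric(length(t_ms))
  on <- t_ms >= onset_ms & t_ms <= offset_ms
  k[on] <- 1 - exp(-(t_ms[on] - onset_ms) / tau_rise_ms)
  post <- t_ms > offset_ms
  if (any(post)) {
    k_off <- 1 - exp(-max(offset_ms - onset_ms, 0) / tau_rise_ms)
    k[post] <- k_off * exp(-(t_ms[post] - offset_ms) / tau_decay_ms)
  }
  k
}

# Session-level static maps: baseline fluorescence, heartbeat spatial
# weight, and the two expression-site profiles. Drawn from the current RNG.
session_maps <- function(geometry, stimulus, texture_sd = 0.08,
                         hb_map_sd = 0.5) {
  ny <- geometry$ny; nx <- geometry$nx
  g1 <- gaussian_site_map(ny, nx, stimulus$site_centers_px[[1]],
                          stimulus$site_fwhm_px)
  g2 <- gaussian_site_map(ny, nx, stimulus$site_centers_px[[2]],
                          stimulus$site_fwhm_px)
  # two texture scales: broad expression unevenness plus fine
  # vasculature-like structure (what image registration latches onto)
  texture <- smooth_random_map(ny, nx, sigma_px = max(2, min(ny, nx) / 16))
  fine <- smooth_random_map(ny, nx, sigma_px = 1.2)
  baseline <- 100 * (1 + 0.2 * g1 + 0.2 * g2 + texture_sd * texture +
                       texture_sd * fine)
  baseline[baseline < 20] <- 20
  hb_map <- 1 + hb_map_sd * smooth_random_map(ny, nx,
                                              sigma_px = max(2, min(ny, nx) / 8))
  list(baseline = baseline, hb_map = hb_map, site1 = g1, site2 = g2)
}

#' Render one synthetic trial stack
#'
#' Applies the forward model for a single trial: site responses (the
#' opsin-expressing site receives visual and optostim drive, with the
#' visual-evoked component scaled by `1 - rho_true` when optostim is on;
#' the indicator-only site receives attenuated visual drive), linear
#' drift, a heart-rate-dependent heartbeat artifact, random-walk
#' micro-motion applied as whole-frame subpixel translation, and additive
#' Gaussian sensor noise.
#'
#' @param ground_truth an `om_ground_truth` (see [ground_truth()]).
#' @param trial one-row data.frame with at least `target_contrast`,
#'   `opto_power_density`, `heart_rate`, `choice`, `saccade_time_ms`,
#'   `condition_id`.
#' @param timeline an `om_timeline`.
#' @param geometry list with `ny`, `nx`, `mm_per_px`.
#' @param maps session static maps from the generator (baseline map,
#'   heartbeat map, site profiles); built once per session.
#' @param seed integer seed for this trial's stochastic components.
#' @return list with `stack` (`ny x nx x n_frames` array) and `sidecar`
#'   (injected motion trace, heartbeat/drift/response time courses, and
#'   the trial's private drift slope) sufficient to reconstruct the
#'   noise-free, motion-free stack exactly.
#' @export
render_trial_stack <- function(ground_truth, trial, timeline, geometry,
                               maps, seed) {
  gt <- ground_truth
  if (gt$rho_true < 0 || gt$rho_true > 1)
    stop("rho_true must be in [0, 1]", call. = FALSE)
  if (geometry$ny < 1 || geometry$nx < 1)
    stop("image dimensions must be positive", call. = FALSE)
  nt <- timeline$n_frames
  t_ms <- timeline$frame_start_ms + timeline$frame_period_ms / 2

  # stimulus/optostim offsets; in the truncating mode both extinguish at
  # the saccade, as the physical stimuli do in the task
  sacc <- if (isTRUE(gt$truncate_at_saccade) &&
              !is.null(trial$saccade_time_ms) &&
              is.finite(trial$saccade_time_ms) &&
              identical(trial$choice, "saccade"))
    trial$saccade_time_ms else Inf
  vis_off <- timeline$stim_onset_ms +
    min(timeline$target_max_duration_ms, sacc)
  opto_off <- min(timeline$opto_onset_ms + timeline$optostim_max_duration_ms,
                  timeline$stim_onset_ms + sacc)

  c_t <- trial$target_contrast
  amp_vis <- if (c_t > 0) naka_rushton(c_t, gt$nr_dff$zmax, gt$nr_dff$n,
                                       gt$nr_dff$c50) else 0
  opto_on <- trial$opto_power_density > 0
  amp_opto <- if (opto_on)
    gt$opto_amplitude[[as.character(trial$opto_power_density)]] %||% 0 else 0

  k_vis <- response_kernel(t_ms, timeline$stim_onset_ms, vis_off)
  k_opto <- if (opto_on)
    response_kernel(t_ms, timeline$opto_onset_ms, opto_off) else numeric(nt)
  r1 <- amp_vis * (1 - gt$rho_true * opto_on) * k_vis + amp_opto * k_opto
  r2 <- gt$site2_visual_gain * amp_vis * k_vis

  # heartbeat temporal profile: fixed waveform locked to acquisition
  # start, amplitude a no-constant polynomial of standardized heart rate
  z <- (trial$heart_rate - gt$hb_hr_center) / gt$hb_hr_scale
  g_hr <- sum(gt$hb_poly * z^seq_along(gt$hb_poly))
  f_hz <- if (gt$hb_phase_mismatch) trial$heart_rate / 60 else
    gt$hb_hr_center / 60
  hb_t <- gt$hb_amplitude * sin(2 * pi * f_hz * t_ms / 1000) * g_hr

  withr_seed(seed, {
    m_k <- stats::rnorm(1, 0, gt$drift_mk_sd)
    steps <- matrix(stats::rnorm(2 * nt, 0, gt$motion_sd_px), 2, nt)
    steps[, 1] <- 0
    v <- t(apply(steps, 1, cumsum))              # 2 x nt, starts at (0,0)
    noise <- if (gt$noise_sd > 0)
      array(stats::rnorm(geometry$ny * geometry$nx * nt, 0, gt$noise_sd),
            dim = c(geometry$ny, geometry$nx, nt)) else 0
  })
  m_s <- gt$drift_ms[[trial$condition_id]] %||% 0
  drift_t <- (m_s + m_k) * t_ms / 1000

  stack <- array(0, dim = c(geometry$ny, geometry$nx, nt))
  B <- maps$baseline
  for (tt in seq_len(nt)) {
    frame <- B * (1 + maps$site1 * r1[tt] + maps$site2 * r2[tt] +
                    drift_t[tt]) + B * maps$hb_map * hb_t[tt]
    if (gt$motion_sd_px > 0)
      frame <- translate_frame(frame, v[1, tt], v[2, tt])
    stack[, , tt] <- frame
  }
  stack <- stack + noise

  list(stack = stack,
       sidecar = list(v = v, hb_t = hb_t, resp1_t = r1, resp2_t = r2,
                      drift_t = drift_t, m_k = m_k, m_s = m_s,
                      noise_sd = gt$noise_sd, seed = seed))
}
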