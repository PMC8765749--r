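#' Build and validate an acquisition/stimulation timeline
#'
#' A timeline describes one trial of the detection task as seen by the
#' imaging system: frame rate and frame count of the camera, the temporal
#' cue, the visual target onset, and the optogenetic stimulation (optostim)
#' pulse train. Defaults reproduce the standard task parameters: 20 Hz
#' acquisition for 1.2 s (24 frames), target onset 250 ms after the cue,
#' optostim onset 290 ms after the cue (a 40 ms delay that compensates for
#' V1 response latency), optostim pulses of 5 ms every 22.5 ms (~44 Hz,
#' 22% duty cycle) extinguished after 210 ms.
#'
#' Times are in milliseconds. `cue_time_ms` is measured from acquisition
#' start (the EKG-locked trigger); `target_onset_ms` and `optostim_onset_ms`
#' are measured from the cue. With the defaults the target onset falls at
#' 350 ms from acquisition start, i.e. at the start of frame F8 (1-based),
#' so the three frames F5-F7 cover 0-150 ms before stimulus onset and are
#' the default dF/F baseline.
#'
#' @param frame_rate_hz camera frame rate (Hz).
#' @param n_frames number of frames acquired per trial.
#' @param cue_time_ms cue time from acquisition start (ms).
#' @param target_onset_ms visual target onset relative to the cue (ms).
#' @param optostim_onset_ms optostim onset relative to the cue (ms).
#' @param target_max_duration_ms maximum visual target duration (ms).
#' @param optostim_max_duration_ms maximum optostim train duration (ms).
#' @param pulse_width_ms optostim pulse width (ms).
#' @param pulse_period_ms optostim pulse period (ms).
#' @param optostim_delay_ms expected `optostim_onset_ms - target_onset_ms`;
#'   a mismatch is a validation error.
#'
#' @return An object of class `om_timeline`: a list with the validated
#'   fields plus derived quantities `duty_cycle` (pulse_width/pulse_period),
#'   `pulse_rate_hz` (1000/pulse_period_ms), `frame_period_ms`,
#'   `frame_start_ms` (0-based frame start times from acquisition start),
#'   `stim_onset_ms` (target onset from acquisition start),
#'   `stim_onset_frame` (1-based index of the first frame at/after target
#'   onset) and `baseline_frames` (the three frames preceding it).
#' @export
#' @examples
#' tl <- build_timeline()
#' round(100 * tl$duty_cycle)   # 22
#' round(tl$pulse_rate_hz)      # 44
build_timeline <- function(frame_rate_hz = 20,
                           n_frames = 24,
                           cue_time_ms = 100,
                           target_onset_ms = 250,
                           optostim_onset_ms = 290,
                           target_max_duration_ms = 250,
                           optostim_max_duration_ms = 210,
                           pulse_width_ms = 5,
                           pulse_period_ms = 22.5,
                           optostim_delay_ms = 40) {
  stop_field <- function(field, msg) {
    stop(sprintf("timeline field `%s`: %s", field, msg), call. = FALSE)
  }
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0)
    stop_field("frame_rate_hz", "must be a positive number")
  if (n_frames < 1) stop_field("n_frames", "must be >= 1")
  if (pulse_width_ms <= 0) stop_field("pulse_width_ms", "must be > 0")
  if (pulse_width_ms > pulse_period_ms)
    stop_field("pulse_width_ms", "exceeds pulse_period_ms")
  if (optostim_max_duration_ms < 0)
    stop_field("optostim_max_duration_ms", "optostim ends before it starts")
  if (target_max_duration_ms < 0)
    stop_field("target_max_duration_ms", "target ends before it starts")
  delay <- optostim_onset_ms - target_onset_ms
  if (abs(delay - optostim_delay_ms) > 1e-9)
    stop_field("optostim_onset_ms",
               sprintf("onset delay is %g ms, expected %g ms",
                       delay, optostim_delay_ms))
  total_ms <- n_frames * (1000 / frame_rate_hz)
  opto_end <- cue_time_ms + optostim_onset_ms + optostim_max_duration_ms
  if (total_ms < opto_end)
    stop_field("n_frames",
               sprintf("acquisition (%g ms) ends before optostim offset (%g ms)",
                       total_ms, opto_end))

  frame_period_ms <- 1000 / frame_rate_hz
  frame_start_ms <- (seq_len(n_frames) - 1) * frame_period_ms
  stim_onset_ms <- cue_time_ms + target_onset_ms
  stim_onset_frame <- which(frame_start_ms >= stim_onset_ms - 1e-9)[1]
  if (is.na(stim_onset_frame) || stim_onset_frame < 4)
    stop_field("cue_time_ms",
               "need at least 3 pre-stimulus frames for the baseline")
  baseline_frames <- (stim_onset_frame - 3):(stim_onset_frame - 1)

  structure(list(
    frame_rate_hz = frame_rate_hz,
    n_frames = n_frames,
    cue_time_ms = cue_time_ms,
    target_onset_ms = target_onset_ms,
    optostim_onset_ms = optostim_onset_ms,
    target_max_duration_ms = target_max_duration_ms,
    optostim_max_duration_ms = optostim_max_duration_ms,
    pulse_width_ms = pulse_width_ms,
    pulse_period_ms = pulse_period_ms,
    optostim_delay_ms = delay,
    duty_cycle = pulse_width_ms / pulse_period_ms,
    pulse_rate_hz = 1000 / pulse_period_ms,
    frame_period_ms = frame_period_ms,
    frame_start_ms = frame_start_ms,
    stim_onset_ms = stim_onset_ms,
    opto_onset_ms = cue_time_ms + optostim_onset_ms,
    stim_onset_frame = stim_onset_frame,
    baseline_frames = baseline_frames,
    total_ms = total_ms
  ), class = "om_timeline")
}

#' Optostim pulse onset times
#'
#' Enumerates the pulse onsets of the optostim train relative to optostim
#' onset: `0, T, 2T, ...` for pulse period `T`, up to (excluding) the
#' maximum train duration.
#'
#' @param timeline an `om_timeline`.
#' @return numeric vector of onset times in ms.
#' @export
pulse_onsets <- function(timeline) {
  stopifnot(inherits(timeline, "om_timeline"))
  seq(0, timeline$optostim_max_duration_ms - 1e-9,
      by = timeline$pulse_period_ms)
}

#' @export
print.om_timeline <- function(x, ...) {
  cat(sprintf(
    "<om_timeline> %d frames @ %g Hz (%g ms)\n", x$n_frames,
    x$frame_rate_hz, x$total_ms))
  cat(sprintf("  cue %g ms | target %g ms | optostim %g ms (delay %g ms)\n",
              x$cue_time_ms, x$stim_onset_ms, x$opto_onset_ms,
              x$optostim_delay_ms))
  cat(sprintf("  pulses %g/%g ms (duty %d%%, %g Hz), train %g ms\n",
              x$pulse_width_ms, x$pulse_period_ms,
              round(100 * x$duty_cycle), round(x$pulse_rate_hz),
              x$optostim_max_duration_ms))
  invisible(x)
}

#' Stimulus specification with Weber contrast
#'
#' Describes the visual Gaussian target and the two opsin/indicator
#' expression sites in image coordinates. Weber contrast is
#' `(L_max - L_background) / L_background`; if both luminances and a
#' contrast are supplied they must agree to 1e-12.
#'
#' @param weber_contrast dimensionless target contrast (>= 0). May be
#'   omitted when both luminances are given.
#' @param background_luminance,target_peak_luminance luminances in cd/m^2.
#' @param target_fwhm_deg full width at half maximum of the Gaussian
#'   target, degrees of visual angle.
#' @param site_centers_px list of two `c(x, y)` pixel pairs: the opsin
#'   (C1V1) expression site, then the indicator-only (GCaMP) site.
#' @param site_fwhm_px FWHM of the expression-site Gaussians, pixels.
#' @return an `om_stimulus` list.
#' @export
stimulus_spec <- function(weber_contrast = NULL,
                          background_luminance = 50,
                          target_peak_luminance = NULL,
                          target_fwhm_deg = 0.33,
                          site_centers_px = list(c(16, 16), c(48, 48)),
                          site_fwhm_px = 12) {
  if (is.null(weber_contrast) && is.null(target_peak_luminance))
    stop("supply weber_contrast or target_peak_luminance", call. = FALSE)
  if (!is.null(target_peak_luminance)) {
    if (background_luminance <= 0)
      stop("background_luminance must be > 0", call. = FALSE)
    c_from_lum <- (target_peak_luminance - background_luminance) /
      background_luminance
    if (is.null(weber_contrast)) {
      weber_contrast <- c_from_lum
    } else if (abs(weber_contrast - c_from_lum) > 1e-12) {
      stop("weber_contrast inconsistent with supplied luminances",
           call. = FALSE)
    }
  }
  if (weber_contrast < 0) stop("weber_contrast must be >= 0", call. = FALSE)
  if (target_fwhm_deg <= 0 || site_fwhm_px <= 0)
    stop("fwhm must be > 0", call. = FALSE)
  if (length(site_centers_px) != 2)
    stop("site_centers_px must list exactly two (x, y) pairs", call. = FALSE)
  structure(list(
    weber_contrast = weber_contrast,
    background_luminance = background_luminance,
    target_peak_luminance = target_peak_luminance %||%
      (background_luminance * (1 + weber_contrast)),
    target_fwhm_deg = target_fwhm_deg,
    site_centers_px = site_centers_px,
    site_fwhm_px = site_fwhm_px
  ), class = "om_stimulus")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
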