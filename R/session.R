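# Session-level configuration and the synthetic-session generator.

#' Ground-truth parameter container for synthetic sessions
#'
#' Collects every generative parameter the downstream pipeline is asked to
#' recover: the psychometric truth per block, the contrast-response
#' (Naka-Rushton) law of the visual dF/F response, the optostim-evoked
#' amplitude per power density, the sublinearity `rho_true` (the fraction
#' by which optostim scales down the visual-evoked component at the opsin
#' site), and the artifact amplitudes (heartbeat, micro-motion, drift,
#' sensor noise).
#'
#' Default amplitudes describe a realistic session: a ~4% peak dF/F
#' visual response, an optostim response of comparable size, a heartbeat
#' artifact of ~0.4% of baseline fluorescence, sub-pixel micro-motion
#' (random-walk step 0.05 px), slow drifts of ~0.2%/s, and sensor noise
#' of 0.3 intensity units on a baseline of ~100.
#'
#' @param rho_true sublinear interaction in `[0, 1]`; 0 = additive, 1 =
#'   complete suppression of the visual-evoked component under optostim.
#' @param psych_params named list of `(alpha, beta, delta)` per block id.
#' @param nr_dff Naka-Rushton parameters `(zmax, n, c50)` of the visual
#'   response in dF/F units.
#' @param opto_amplitude named list: dF/F amplitude per power density.
#' @param site2_visual_gain visual gain of the indicator-only site
#'   relative to the opsin site.
#' @param hb_amplitude heartbeat modulation amplitude (fraction of
#'   baseline fluorescence).
#' @param hb_poly coefficients (linear..quartic, no constant term) of the
#'   heartbeat amplitude polynomial in standardized heart rate.
#' @param hb_hr_center,hb_hr_scale heart-rate standardization (beats/min).
#' @param hb_phase_mismatch if `TRUE` the heartbeat waveform frequency
#'   follows each trial's heart rate (accordion stretching) instead of the
#'   session mean; a deliberate model-mismatch mode for robustness tests.
#' @param truncate_at_saccade if `TRUE`, the rendered visual and optostim
#'   responses extinguish at the saccade (as the physical stimuli do in
#'   the task). Default `FALSE`: responses run to their maximum
#'   durations, so the optostim component is identical between
#'   optostim-only and combined trials and the proportional-reduction
#'   statistic is unbiased; the truncating mode exists to study that bias.
#' @param motion_sd_px random-walk step SD of the micro-motion (pixels).
#' @param drift_ms_sd SD of the per-condition drift slope (dF/F per s).
#' @param drift_mk_sd SD of the per-trial drift slope (dF/F per s).
#' @param noise_sd additive Gaussian sensor noise SD (intensity units).
#' @param drift_ms optional named list of per-condition slopes; drawn by
#'   the generator when `NULL`.
#' @return an `om_ground_truth` list.
#' @export
ground_truth <- function(rho_true = 0.5,
                         psych_params = list(
                           visual = list(alpha = 0.1, beta = 1.5,
                                         delta = 0.1),
                           opto = list(alpha = 0.15, beta = 1.5,
                                       delta = 0.3)),
                         nr_dff = list(zmax = 0.04, n = 1.5, c50 = 0.15),
                         opto_amplitude = list("0.6" = 0.03),
                         site2_visual_gain = 0.6,
                         hb_amplitude = 0.004,
                         hb_poly = c(1, 0.3, 0, 0),
                         hb_hr_center = 150, hb_hr_scale = 10,
                         hb_phase_mismatch = FALSE,
                         truncate_at_saccade = FALSE,
                         motion_sd_px = 0.05,
                         drift_ms_sd = 0.002,
                         drift_mk_sd = 0.002,
                         noise_sd = 0.3,
                         drift_ms = NULL) {
  if (rho_true < 0 || rho_true > 1)
    stop("rho_true must be in [0, 1]", call. = FALSE)
  for (p in psych_params)
    if (p$alpha <= 0 || p$beta <= 0)
      stop("psychometric alpha and beta must be > 0", call. = FALSE)
  stopifnot(length(hb_poly) == 4, hb_hr_scale > 0,
            motion_sd_px >= 0, noise_sd >= 0)
  structure(list(
    rho_true = rho_true, psych_params = psych_params, nr_dff = nr_dff,
    opto_amplitude = opto_amplitude, site2_visual_gain = site2_visual_gain,
    hb_amplitude = hb_amplitude, hb_poly = hb_poly,
    hb_hr_center = hb_hr_center, hb_hr_scale = hb_hr_scale,
    hb_phase_mismatch = hb_phase_mismatch,
    truncate_at_saccade = truncate_at_saccade,
    motion_sd_px = motion_sd_px, drift_ms_sd = drift_ms_sd,
    drift_mk_sd = drift_mk_sd, noise_sd = noise_sd,
    drift_ms = drift_ms
  ), class = "om_ground_truth")
}

#' Session configuration
#'
#' Aggregates the acquisition geometry, the trial timeline, the condition
#' design, and the analysis constants. Defaults reproduce the standard
#' experiment: 20 Hz acquisition for 1.2 s, dF/F baseline = the three
#' frames before stimulus onset (F5-F7 at the default timing), response
#' window 50-200 ms post-stimulus, 1 x 1 mm^2 ROI, proportion rescaling
#' constants (0.005, 0.99), and 1000 bootstrap resamples.
#'
#' The default desk-scale geometry is 64 x 64 px covering a 2 x 2 mm
#' field (1/32 mm per pixel), so the standard 1 x 1 mm^2 ROI is a 32 px
#' window that the ROI search can actually place. (A field of exactly
#' 1 x 1 mm would make the ROI the whole image and would force the two
#' expression sites — separate cortical locations in reality — into a
#' single ROI.)
#'
#' @param nx,ny image size (pixels).
#' @param mm_per_px pixel pitch in mm.
#' @param timeline an `om_timeline`; default [build_timeline()].
#' @param stimulus an `om_stimulus`; the default places the opsin site at
#'   (16, 16) and the indicator-only site at (48, 48), 1.4 mm apart.
#' @param contrasts Weber contrast levels; contrast 0 rows are the blank /
#'   optostim-only conditions.
#' @param opto_powers optostim power densities (mW/mm^2), one optostim
#'   block per level.
#' @param n_per_cond trials per (block x contrast) condition.
#' @param target_present_frac fraction of target-present trials at each
#'   non-zero contrast.
#' @param hr_mean,hr_sd per-trial heart-rate distribution (beats/min).
#' @param saccade_median_ms,saccade_sdlog log-normal reaction-time model
#'   (ms from target onset), truncated to the task's 75-600 ms window.
#' @param roi_mm ROI side length (mm).
#' @param response_window_ms response window relative to stimulus onset,
#'   half-open `[lo, hi)`.
#' @param roi_window_ms window (ms post-stimulus) of the map used for
#'   ROI *selection*. It is deliberately disjoint from
#'   `response_window_ms`: selecting the maximizing window on the same
#'   frames that are then averaged into the response would inflate the
#'   visual-only responses by the selection optimum's noise (winner's
#'   curse) and bias the reduction statistic upward. The GCaMP response
#'   is sustained, so the late window carries the same spatial map.
#' @param n_boot bootstrap resamples for inference.
#' @param ground_truth an `om_ground_truth`.
#' @return an `om_config` list.
#' @export
session_config <- function(nx = 64, ny = 64, mm_per_px = 1 / 32,
                           timeline = build_timeline(),
                           stimulus = stimulus_spec(weber_contrast = 0.2),
                           contrasts = c(0, 0.05, 0.1, 0.2, 0.4),
                           opto_powers = 0.6,
                           n_per_cond = 20,
                           target_present_frac = 0.5,
                           hr_mean = 150, hr_sd = 10,
                           saccade_median_ms = 160, saccade_sdlog = 0.35,
                           roi_mm = 1,
                           response_window_ms = c(50, 200),
                           roi_window_ms = c(200, 400),
                           n_boot = 1000,
                           ground_truth = NULL) {
  if (is.null(ground_truth)) {
    ground_truth <- eval(call("ground_truth"))  # package default truth
  }
  stopifnot(nx >= 4, ny >= 4, mm_per_px > 0, n_per_cond >= 1)
  if (!0 %in% contrasts)
    stop("configuration error: contrasts must include 0 ",
         "(blank / optostim-only trials are required downstream)",
         call. = FALSE)
  structure(list(
    geometry = list(nx = nx, ny = ny, mm_per_px = mm_per_px),
    timeline = timeline, stimulus = stimulus,
    contrasts = sort(unique(contrasts)), opto_powers = opto_powers,
    n_per_cond = n_per_cond, target_present_frac = target_present_frac,
    hr_mean = hr_mean, hr_sd = hr_sd,
    saccade_median_ms = saccade_median_ms, saccade_sdlog = saccade_sdlog,
    roi_mm = roi_mm, response_window_ms = response_window_ms,
    roi_window_ms = roi_window_ms,
    n_boot = n_boot, rescale_lo = 0.005, rescale_slope = 0.99,
    ground_truth = ground_truth
  ), class = "om_config")
}

# Map a power density to its block id and psychometric parameter key.
opto_block_id <- function(power) paste0("opto", power)

# Imaging condition of a trial: what was physically presented.
condition_id_of <- function(block_id, target_contrast) {
  paste0(block_id, "_c", target_contrast)
}

#' Build the trial table for a session design
#'
#' Enumerates trials over blocks (one visual-only block plus one block per
#' optostim power; optostim is on on *every* trial of an optostim block),
#' contrasts, and target presence, then assigns heart rates and a shuffled
#' order. Contrast-0 rows are fully target-absent: in the visual block
#' they are blank trials, in optostim blocks they are optostim-only
#' baseline trials.
#'
#' @param config an `om_config`.
#' @param seed integer seed.
#' @return data.frame of trial records (choices unfilled).
#' @export
build_trial_table <- function(config, seed = 1L) {
  rows <- list()
  blocks <- c(list(list(id = "visual", power = 0)),
              lapply(config$opto_powers,
                     function(p) list(id = opto_block_id(p), power = p)))
  withr_seed(seed, {
    for (blk in blocks) {
      for (cc in config$contrasts) {
        n <- config$n_per_cond
        present <- if (cc > 0)
          stats::runif(n) < config$target_present_frac else rep(FALSE, n)
        rows[[length(rows) + 1]] <- data.frame(
          block_id = blk$id,
          block_contrast = cc,
          target_present = present,
          target_contrast = ifelse(present, cc, 0),
          opto_power_density = blk$power,
          heart_rate = stats::rnorm(n, config$hr_mean, config$hr_sd),
          stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    tab <- tab[sample.int(nrow(tab)), , drop = FALSE]
  })
  tab$trial_id <- seq_len(nrow(tab))
  tab$condition_id <- condition_id_of(tab$block_id, tab$target_contrast)
  rownames(tab) <- NULL
  tab[, c("trial_id", "block_id", "condition_id", "target_present",
          "target_contrast", "block_contrast", "opto_power_density",
          "heart_rate")]
}

# Draw saccade times (ms from target onset) for saccade choices; log-normal
# truncated to the allowed 75-600 ms reaction window.
draw_saccade_times <- function(trial_table, config, seed) {
  n <- nrow(trial_table)
  withr_seed(seed, {
    st <- stats::rlnorm(n, log(config$saccade_median_ms),
                        config$saccade_sdlog)
  })
  st <- pmin(pmax(st, 75), 600)
  ifelse(trial_table$choice == "saccade", st, NA_real_)
}

#' Generate a complete synthetic session
#'
#' Produces the three artifacts the pipeline consumes: per-trial image
#' stacks, the trial metadata table (with behavioral outcomes simulated
#' from the psychometric ground truth), and the ground-truth sidecar
#' (injected parameters, per-trial motion/artifact/response time courses,
#' and the session's static maps).
#'
#' Reproducibility: one session seed deterministically expands into
#' per-purpose child seeds (maps, trial table, choices, per-trial
#' renders), so any single trial can be re-rendered in isolation.
#'
#' @param config an `om_config`.
#' @param seed integer session seed.
#' @param render_stacks set `FALSE` for behavior-only sessions (no
#'   imaging; much faster).
#' @return an `om_session` list with elements `stacks` (list of
#'   `ny x nx x n_frames` arrays, named by trial id), `trials`
#'   (data.frame), `config`, `ground_truth`, `maps`, `sidecars`, `seed`.
#' @export
generate_session <- function(config, seed = 1L, render_stacks = TRUE) {
  gt <- config$ground_truth
  tab <- build_trial_table(config, seed = child_seed(seed, 1))

  # behavioral outcomes: the optostim blocks use their own (alpha, delta)
  psych <- list(visual = gt$psych_params$visual)
  for (p in config$opto_powers) {
    key <- opto_block_id(p)
    psych[[key]] <- gt$psych_params[[key]] %||% gt$psych_params$opto
  }
  tab <- simulate_choices(tab, psych, seed = child_seed(seed, 2))
  tab$saccade_time_ms <- draw_saccade_times(tab, config,
                                            seed = child_seed(seed, 3))

  # per-condition drift slopes (drawn once per session unless supplied)
  conds <- unique(tab$condition_id)
  if (is.null(gt$drift_ms)) {
    withr_seed(child_seed(seed, 4), {
      gt$drift_ms <- stats::setNames(
        as.list(stats::rnorm(length(conds), 0, gt$drift_ms_sd)), conds)
    })
  }

  maps <- NULL; stacks <- NULL; sidecars <- NULL
  if (render_stacks) {
    withr_seed(child_seed(seed, 5), {
      maps <- session_maps(config$geometry, config$stimulus)
    })
    stacks <- vector("list", nrow(tab))
    sidecars <- vector("list", nrow(tab))
    for (i in seq_len(nrow(tab))) {
      r <- render_trial_stack(gt, tab[i, ], config$timeline,
                              config$geometry, maps,
                              seed = child_seed(seed, 100 + tab$trial_id[i]))
      stacks[[i]] <- r$stack
      sidecars[[i]] <- r$sidecar
    }
    names(stacks) <- names(sidecars) <- as.character(tab$trial_id)
  }

  structure(list(stacks = stacks, trials = tab, config = config,
                 ground_truth = gt, maps = maps, sidecars = sidecars,
                 seed = seed, stages = character(0)),
            class = "om_session")
}

#' @export
print.om_session <- function(x, ...) {
  g <- x$config$geometry
  cat(sprintf("<om_session> %d trials, %s, seed %d\n", nrow(x$trials),
              if (is.null(x$stacks)) "no stacks" else
                sprintf("%dx%dx%d stacks", g$ny, g$nx,
                        x$config$timeline$n_frames), x$seed))
  if (length(x$stages))
    cat("  stages applied:", paste(x$stages, collapse = " -> "), "\n")
  invisible(x)
}
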