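# From cleaned stacks to per-trial scalar responses and z-scores.

#' Compute dF/F for a trial stack
#'
#' `dF/F(t) = (F(t) - F0) / F0` per pixel, with `F0` the average
#' fluorescence over the baseline frames (by default the three frames
#' covering 0-150 ms before stimulus onset: F5-F7 at the standard 20 Hz
#' timing with onset at F8).
#'
#' @param stack `ny x nx x nt` array of raw fluorescence.
#' @param baseline_frames integer frame indices (1-based) averaged into F0.
#' @return list `dff` (array, same shape) and `baseline_frames`; the mean
#'   of the baseline frames of `dff` is 0 by construction.
#' @export
compute_dff <- function(stack, baseline_frames) {
  d <- dim(stack)
  stopifnot(length(d) == 3, all(baseline_frames >= 1),
            all(baseline_frames <= d[3]))
  f0 <- apply(stack[, , baseline_frames, drop = FALSE], c(1, 2), mean)
  nbad <- sum(f0 <= 0)
  if (nbad > 0)
    stop(sprintf("F0 <= 0 at %d pixel(s); cannot divide", nbad),
         call. = FALSE)
  dff <- sweep(sweep(stack, c(1, 2), f0, "-"), c(1, 2), f0, "/")
  list(dff = dff, baseline_frames = baseline_frames)
}

#' Convert a session's stacks to dF/F
#'
#' @param session an `om_session`.
#' @param baseline_frames defaults to the timeline's three pre-stimulus
#'   frames.
#' @return the session with dF/F stacks and `"dff"` appended to `$stages`.
#' @export
dff_session <- function(session, baseline_frames = NULL) {
  stopifnot(inherits(session, "om_session"), !is.null(session$stacks))
  bf <- baseline_frames %||% session$config$timeline$baseline_frames
  session$stacks <- lapply(session$stacks,
                           function(s) compute_dff(s, bf)$dff)
  session$baseline_frames <- bf
  session$stages <- c(session$stages, "dff")
  session
}

#' Select the best-response ROI by exhaustive window search
#'
#' Slides a `w x w` pixel window (`w = round(roi_mm / mm_per_px)`) over a
#' response map and returns the window with the largest mean. Ties are
#' broken by the smallest `(y0, x0)` lexicographically (y first). The
#' search uses an integral image, so it is exact and exhaustive.
#'
#' @param response_map matrix, typically the visual-condition mean dF/F
#'   averaged over the response window.
#' @param roi_mm window side length in mm (default 1, the standard
#'   1 x 1 mm^2 ROI).
#' @param mm_per_px pixel pitch.
#' @return an `om_roi` list: `x0`, `y0` (1-based top-left corner),
#'   `width_px`, `height_px`, `roi_mm`, `mm_per_px`, `mean`.
#' @export
select_roi <- function(response_map, roi_mm = 1, mm_per_px = 1 / 64) {
  ny <- nrow(response_map); nx <- ncol(response_map)
  w <- max(1L, as.integer(round(roi_mm / mm_per_px)))
  if (w > ny || w > nx)
    stop("ROI larger than image", call. = FALSE)
  S <- window_means(response_map, w)       # (ny-w+1) x (nx-w+1)
  # lexicographic (y0, x0) tie-break: scan rows first
  best <- -Inf; by <- 1L; bx <- 1L
  for (y0 in seq_len(nrow(S))) {
    row <- S[y0, ]
    x0 <- which.max(row)
    if (row[x0] > best + 1e-12) { best <- row[x0]; by <- y0; bx <- x0 }
  }
  structure(list(x0 = bx, y0 = by, width_px = w, height_px = w,
                 roi_mm = roi_mm, mm_per_px = mm_per_px, mean = best),
            class = "om_roi")
}

# Mean of every w x w window via a padded integral image.
window_means <- function(m, w) {
  ny <- nrow(m); nx <- ncol(m)
  ii <- matrix(0, ny + 1, nx + 1)
  ii[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  y0 <- seq_len(ny - w + 1); x0 <- seq_len(nx - w + 1)
  (ii[y0 + w, x0 + w, drop = FALSE] - ii[y0, x0 + w, drop = FALSE] -
      ii[y0 + w, x0, drop = FALSE] + ii[y0, x0, drop = FALSE]) / w^2
}

# Mean dF/F map over the response window for a set of trials.
response_map_of <- function(stacks, idx, window_frames) {
  acc <- 0
  for (i in idx)
    acc <- acc + apply(stacks[[i]][, , window_frames, drop = FALSE],
                       c(1, 2), mean)
  acc / length(idx)
}

#' Frames covered by a post-stimulus window
#'
#' Returns the frames whose start times fall in the half-open interval
#' `[lo, hi)` ms after stimulus onset; the standard 50-200 ms window is
#' exactly three frames at 20 Hz.
#'
#' @param timeline an `om_timeline`.
#' @param window_ms `c(lo, hi)` in ms relative to stimulus onset.
#' @return integer frame indices.
#' @export
window_frames_of <- function(timeline, window_ms = c(50, 200)) {
  if (window_ms[2] <= window_ms[1] || window_ms[1] < 0)
    stop("invalid response window", call. = FALSE)
  rel <- timeline$frame_start_ms - timeline$stim_onset_ms
  fr <- which(rel >= window_ms[1] - 1e-9 & rel < window_ms[2] - 1e-9)
  if (!length(fr))
    stop("response window covers no whole frame", call. = FALSE)
  fr
}

#' Summarize a trial time course over the response window
#'
#' Mean of the frames whose start times lie in the (half-open) window,
#' the scalar neural response used for all downstream statistics.
#'
#' @param timecourse numeric vector, one value per frame.
#' @param timeline an `om_timeline`.
#' @param window_ms window in ms post-stimulus, default `c(50, 200)`.
#' @return scalar.
#' @export
summarize_response <- function(timecourse, timeline,
                               window_ms = c(50, 200)) {
  mean(timecourse[window_frames_of(timeline, window_ms)])
}

#' Detrend ROI time courses
#'
#' Removes slow linear drifts with the two-component model
#' `R(t) = R_S(t) + m_S(t) + m_k * t`: a per-condition affine component
#' `m_S` estimated on pre-stimulus frames (constraining every conditional
#' mean to a flat, zero pre-stimulus baseline) and a per-trial linear
#' component `m_k` estimated by least squares on the trial's residual from
#' its conditional mean, using frames up to the saccade. Each trial is
#' first anchored by subtracting its own pre-stimulus mean.
#'
#' @param timecourses `n_trials x n_frames` matrix of ROI-mean responses.
#' @param conditions character vector of condition ids per trial.
#' @param pre_frames integer indices of pre-stimulus frames.
#' @param frame_times_ms frame start times (ms).
#' @param valid_mask optional logical matrix (same shape): frames usable
#'   per trial (monotone: once invalid, stays invalid). Defaults to all
#'   valid.
#' @return an `om_timecourses` list: `timecourses` (detrended matrix),
#'   `conditions`, `m_s` (per-condition intercept/slope), `m_k` (per-trial
#'   slope), `flagged` (trials with < 2 valid frames, for which `m_k = 0`).
#' @export
detrend <- function(timecourses, conditions, pre_frames, frame_times_ms,
                    valid_mask = NULL) {
  R <- as.matrix(timecourses)
  n <- nrow(R); nt <- ncol(R)
  stopifnot(length(conditions) == n, length(frame_times_ms) == nt)
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, n, nt)
  t_s <- frame_times_ms / 1000

  # (0) pre-stimulus anchoring per trial
  R <- R - rowMeans(R[, pre_frames, drop = FALSE])

  # (1) per-condition affine correction from pre-stimulus conditional mean
  conds <- unique(conditions)
  m_s <- stats::setNames(vector("list", length(conds)), conds)
  for (cd in conds) {
    idx <- which(conditions == cd)
    cm_pre <- colMeans(R[idx, pre_frames, drop = FALSE])
    tp <- t_s[pre_frames]
    b <- if (length(pre_frames) >= 2 && stats::sd(tp) > 0)
      stats::cov(tp, cm_pre) / stats::var(tp) else 0
    a <- mean(cm_pre) - b * mean(tp)
    R[idx, ] <- R[idx, ] - rep(a + b * t_s, each = length(idx))
    m_s[[cd]] <- c(intercept = a, slope = b)
  }

  # (2) per-trial residual line on valid frames
  m_k <- numeric(n)
  flagged <- integer(0)
  cond_mean <- matrix(0, length(conds), nt, dimnames = list(conds, NULL))
  for (cd in conds)
    cond_mean[cd, ] <- colMeans(R[conditions == cd, , drop = FALSE])
  for (k in seq_len(n)) {
    v <- which(valid_mask[k, ])
    e <- R[k, ] - cond_mean[conditions[k], ]
    if (length(v) < 2 || stats::sd(t_s[v]) == 0) {
      flagged <- c(flagged, k)
      next
    }
    b <- stats::cov(t_s[v], e[v]) / stats::var(t_s[v])
    a <- mean(e[v]) - b * mean(t_s[v])
    m_k[k] <- b
    R[k, ] <- R[k, ] - (a + b * t_s)
  }

  structure(list(timecourses = R, conditions = conditions, m_s = m_s,
                 m_k = m_k, flagged = flagged, pre_frames = pre_frames,
                 frame_times_ms = frame_times_ms,
                 valid_mask = valid_mask),
            class = "om_timecourses")
}

#' Z-score scalar responses against the blank trials
#'
#' `z = (R - mean(R_blank)) / sd(R_blank)` with the unbiased (n-1) SD
#' estimator; blank = no visual target and no optostim, from the same
#' experiment. Z-scores from different experiments can then be pooled.
#'
#' @param responses numeric vector of scalar responses, all trials.
#' @param is_blank logical vector marking the blank trials (>= 2 required).
#' @return list `z` (vector), `mean_blank`, `sd_blank`.
#' @export
zscore_responses <- function(responses, is_blank) {
  if (sum(is_blank) < 2)
    stop("need >= 2 blank trials for z-scoring", call. = FALSE)
  m <- mean(responses[is_blank])
  s <- stats::sd(responses[is_blank])
  if (s == 0) stop("sigma_blank is zero", call. = FALSE)
  list(z = (responses - m) / s, mean_blank = m, sd_blank = s)
}

#' Extract per-trial responses and z-scores from a preprocessed session
#'
#' Selects the ROI on the visual-only condition-mean map (pooled over
#' non-zero-contrast, target-present, no-optostim trials), averages each
#' trial's stack within the ROI into a time course, detrends, summarizes
#' over the response window, and z-scores against the blanks.
#'
#' @param session an `om_session` whose stacks are dF/F (heartbeat
#'   removal applied or not).
#' @param roi optionally a precomputed `om_roi`.
#' @return the session with `$responses` (data.frame: trial_id, block_id,
#'   condition_id, contrast columns, `R`, `z`), `$roi`, `$timecourses`
#'   attached, and `"extract"` appended to `$stages`.
#' @export
extract_session <- function(session, roi = NULL) {
  stopifnot(inherits(session, "om_session"), !is.null(session$stacks))
  tl <- session$config$timeline
  wf <- window_frames_of(tl, session$config$response_window_ms)
  trials <- session$trials

  if (is.null(roi)) {
    vis_idx <- which(trials$target_present &
                       trials$opto_power_density == 0)
    if (!length(vis_idx))
      stop("no visual-only target-present trials for ROI selection",
           call. = FALSE)
    # ROI selection uses a window disjoint from the response window:
    # maximizing over the response frames themselves would add the
    # selection optimum's noise to the visual responses (winner's curse)
    wf_roi <- window_frames_of(
      tl, session$config$roi_window_ms %||% c(200, 400))
    rmap <- response_map_of(session$stacks, vis_idx, wf_roi)
    roi <- select_roi(rmap, session$config$roi_mm,
                      session$config$geometry$mm_per_px)
  }
  ys <- roi$y0 + seq_len(roi$height_px) - 1
  xs <- roi$x0 + seq_len(roi$width_px) - 1
  tc <- t(vapply(session$stacks, function(s)
    colMeans(matrix(s[ys, xs, ], length(ys) * length(xs), dim(s)[3])),
    numeric(tl$n_frames)))

  # frames valid up to the saccade (stimulus and optostim extinguish then)
  valid <- matrix(TRUE, nrow(tc), tl$n_frames)
  for (k in seq_len(nrow(tc))) {
    st <- trials$saccade_time_ms[k]
    if (is.finite(st) && !is.na(st))
      valid[k, ] <- tl$frame_start_ms < tl$stim_onset_ms + st
  }

  # detrending uses *all* pre-stimulus frames (F1-F7 at the default
  # timing), not just the three F0 baseline frames: the per-condition
  # affine is extrapolated into the response window, and a 3-point fit
  # amplifies pre-stimulus noise ~4x
  det <- detrend(tc, trials$condition_id,
                 pre_frames = seq_len(tl$stim_onset_frame - 1),
                 frame_times_ms = tl$frame_start_ms,
                 valid_mask = valid)
  R <- apply(det$timecourses, 1, function(v)
    summarize_response(v, tl, session$config$response_window_ms))
  blank <- !trials$target_present & trials$opto_power_density == 0
  zs <- zscore_responses(R, blank)

  session$responses <- data.frame(
    trial_id = trials$trial_id, block_id = trials$block_id,
    condition_id = trials$condition_id,
    target_present = trials$target_present,
    target_contrast = trials$target_contrast,
    block_contrast = trials$block_contrast,
    opto_power_density = trials$opto_power_density,
    R = R, z = zs$z, stringsAsFactors = FALSE)
  session$roi <- roi
  session$timecourses <- det
  # pre-detrend ROI time courses, kept for bootstrap replicates that
  # re-run the detrend -> summarize -> z-score tail of the analysis
  session$timecourses_raw <- tc
  session$valid_mask <- valid
  session$zscore <- zs[c("mean_blank", "sd_blank")]
  session$stages <- c(session$stages, "extract")
  session
}
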