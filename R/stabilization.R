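# Motion-regression image stabilization.
#
# Each pixel's intensity over a trial is modelled with separable
# motion-free and motion-related components,
#   I[x,y,t] = I0[x,y,t] + alpha[x,y] . v[t],
# where v[t] is a single global translation estimated from the center
# portion of the images (1/4 of the imaging area) and alpha[x,y] is a
# per-pixel 2-vector of least-squares coefficients. Stabilization
# subtracts the motion-related component; because it is a per-pixel
# regression rather than a resampling, it also captures small non-rigid
# deformations to first order.

#' Estimate the per-frame global motion trace of a stack
#'
#' Cross-correlates the center crop (half width x half height, i.e. 1/4 of
#' the imaging area) of every frame against the trial-median frame, using
#' FFT cross-correlation with parabolic sub-pixel peak interpolation. The
#' returned trace is median-centered per axis, so the implicit reference
#' frame has motion (0, 0).
#'
#' @param stack `ny x nx x nt` array, `nt >= 2`.
#' @param max_shift_px largest credible shift; the correlation peak is
#'   searched within this radius.
#' @param highpass_sigma_px frames are spatially high-passed (Gaussian
#'   blur of this sigma subtracted) before correlation, so that broad
#'   stimulus-evoked fluorescence changes — which are spatially
#'   asymmetric within the crop and masquerade as image shift — do not
#'   bias the estimate, while fine vascular texture is preserved. Set to
#'   `0` to disable.
#' @return an `om_motion_trace`: `2 x nt` matrix (rows x, y) with
#'   attribute `warning` set to `"constant_crop"` when the crop had zero
#'   variance (all-zero trace returned).
#'
#' @details The raw trial-median frame is blurred by the very motion
#'   being estimated, so estimation is two-pass: consecutive-frame shifts
#'   are integrated into a provisional trace, every frame is de-shifted,
#'   and the average of the de-shifted frames serves as the sharp
#'   reference for the final per-frame estimates.
#' @export
estimate_motion <- function(stack, max_shift_px = 5,
                            highpass_sigma_px = 3) {
  d <- dim(stack)
  if (length(d) != 3 || d[3] < 2)
    stop("stack must be ny x nx x nt with nt >= 2", call. = FALSE)
  ny <- d[1]; nx <- d[2]; nt <- d[3]
  ys <- floor(ny / 4) + seq_len(floor(ny / 2))
  xs <- floor(nx / 4) + seq_len(floor(nx / 2))
  crop <- stack[ys, xs, , drop = FALSE]
  if (highpass_sigma_px > 0)
    for (tt in seq_len(nt))
      crop[, , tt] <- highpass2d(crop[, , tt], highpass_sigma_px)
  if (stats::sd(crop) == 0) {
    v <- matrix(0, 2, nt)
    attr(v, "warning") <- "constant_crop"
    class(v) <- c("om_motion_trace", class(v))
    return(v)
  }
  # pass 1: consecutive-frame shifts (sharp pairs), integrated into a
  # provisional trace. The raw trial-median frame is blurred by the very
  # motion being estimated, so it is a poor direct reference.
  v <- matrix(0, 2, nt)
  for (tt in 2:nt)
    v[, tt] <- v[, tt - 1] +
      xcorr_shift(crop[, , tt], crop[, , tt - 1], max_shift_px)
  # pass 2: re-estimate every frame against the average of de-shifted
  # frames (sharp once de-shifted), which removes the integration drift
  desh <- matrix(0, length(ys) * length(xs), nt)
  for (tt in seq_len(nt))
    desh[, tt] <- translate_frame(crop[, , tt], -v[1, tt], -v[2, tt])
  ref <- matrix(rowMeans(desh), length(ys), length(xs))
  for (tt in seq_len(nt))
    v[, tt] <- xcorr_shift(crop[, , tt], ref, max_shift_px)
  v <- v - apply(v, 1, stats::median)
  class(v) <- c("om_motion_trace", class(v))
  v
}

# FFT circular cross-correlation shift of `frame` relative to `ref`
# (positive = content moved right/down), with parabolic refinement.
# Clamped (non-periodic) edges bias a single correlation toward zero by
# a few percent of the shift, so the estimate is refined iteratively
# against the reference translated by the running estimate (the residual
# bias shrinks geometrically).
xcorr_shift <- function(frame, ref, max_shift, n_iter = 4) {
  w <- hann2d(nrow(frame), ncol(frame))   # suppress edge discontinuity
  f0 <- w * (frame - mean(frame))
  ff <- stats::fft(f0)
  v <- c(0, 0)
  for (it in seq_len(n_iter)) {
    r <- if (all(v == 0)) ref else translate_frame(ref, v[1], v[2])
    r0 <- w * (r - mean(r))
    cc <- Re(stats::fft(ff * Conj(stats::fft(r0)), inverse = TRUE)) /
      length(f0)
    step <- correlation_peak(cc, max_shift)
    v <- v + step
    # edge bias is proportional to the residual shift (~8% of it), so
    # refinement below ~0.3 px buys nothing at the 0.1 px accuracy target
    if (max(abs(step)) < 0.3) break
  }
  v
}

# subtract a periodic Gaussian blur (FFT transfer function)
highpass2d <- function(m, sigma_px) {
  ny <- nrow(m); nx <- ncol(m)
  fy <- c(0:floor(ny / 2), -(ceiling(ny / 2) - 1):-1) / ny
  fx <- c(0:floor(nx / 2), -(ceiling(nx / 2) - 1):-1) / nx
  h <- exp(-2 * pi^2 * sigma_px^2 *
             (outer(fy^2, rep(1, nx)) + outer(rep(1, ny), fx^2)))
  m - Re(stats::fft(stats::fft(m) * h, inverse = TRUE)) / (ny * nx)
}

hann2d <- local({
  cache <- list()
  function(ny, nx) {
    key <- paste(ny, nx)
    if (is.null(cache[[key]])) {
      hy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ny) - 1) / (ny - 1))
      hx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nx) - 1) / (nx - 1))
      cache[[key]] <<- outer(hy, hx)
    }
    cache[[key]]
  }
})

# Locate the cross-correlation peak within +-max_shift and refine each
# axis with a 3-point parabolic fit. `cc` is in FFT order: shift s maps to
# index s+1 (mod n).
correlation_peak <- function(cc, max_shift) {
  ny <- nrow(cc); nx <- ncol(cc)
  sy <- c(0:min(max_shift, ny - 1),
          if (max_shift > 0) -(1:min(max_shift, ny - 1)))
  sx <- c(0:min(max_shift, nx - 1),
          if (max_shift > 0) -(1:min(max_shift, nx - 1)))
  sy <- unique(sy); sx <- unique(sx)
  iy <- (sy %% ny) + 1; ix <- (sx %% nx) + 1
  sub <- cc[iy, ix, drop = FALSE]
  k <- arrayInd(which.max(sub), dim(sub))
  py <- sy[k[1]]; px <- sx[k[2]]
  y <- refine_axis(cc, py, px, "y")
  x <- refine_axis(cc, py, px, "x")
  c(x, y)
}

refine_axis <- function(cc, py, px, axis) {
  ny <- nrow(cc); nx <- ncol(cc)
  if (axis == "y") {
    i <- function(p) cc[(p %% ny) + 1, (px %% nx) + 1]
    p <- py
  } else {
    i <- function(p) cc[(py %% ny) + 1, (p %% nx) + 1]
    p <- px
  }
  c0 <- i(p); cm <- i(p - 1); cp <- i(p + 1)
  den <- cm - 2 * c0 + cp
  if (is.finite(den) && den < 0) p + 0.5 * (cm - cp) / den else p
}

#' Fit per-pixel motion coefficients
#'
#' Least-squares regression, per pixel, of intensity on the motion trace
#' `(v_x(t), v_y(t))` with an intercept (discarded). To keep the
#' stimulus-evoked signal out of the fit, only frames where the
#' stimulus-driven component is constant are used: by default the
#' pre-stimulus frames of every trial plus all frames of blank trials,
#' pooled across the session.
#'
#' @param stacks list of `ny x nx x nt` arrays.
#' @param traces list of `2 x nt` motion traces (same order).
#' @param fit_frames list of integer vectors: the frames of each trial to
#'   include. Defaults to all frames.
#' @return an `om_motion_coeffs`: `ny x nx x 2` array (x, y coefficient
#'   planes) with attribute `dropped_axes` naming any axis dropped for
#'   lack of motion variance.
#' @export
fit_motion_coefficients <- function(stacks, traces, fit_frames = NULL) {
  stopifnot(length(stacks) == length(traces))
  if (is.null(fit_frames))
    fit_frames <- lapply(stacks, function(s) seq_len(dim(s)[3]))
  d <- dim(stacks[[1]])
  ny <- d[1]; nx <- d[2]
  vx <- unlist(lapply(seq_along(stacks),
                      function(i) traces[[i]][1, fit_frames[[i]]]))
  vy <- unlist(lapply(seq_along(stacks),
                      function(i) traces[[i]][2, fit_frames[[i]]]))
  nfr <- length(vx)
  if (nfr < 3)
    stop("need >= 3 pooled frames to fit motion coefficients",
         call. = FALSE)
  Y <- matrix(0, nfr, ny * nx)
  at <- 0
  for (i in seq_along(stacks)) {
    fr <- fit_frames[[i]]
    if (!length(fr)) next
    Y[at + seq_along(fr), ] <- t(matrix(stacks[[i]][, , fr, drop = FALSE],
                                        ny * nx, length(fr)))
    at <- at + length(fr)
  }
  dropped <- character(0)
  use_x <- stats::sd(vx) > 1e-12
  use_y <- stats::sd(vy) > 1e-12
  X <- cbind(intercept = 1,
             if (use_x) vx, if (use_y) vy)
  # near-collinear traces: drop the second axis and flag it
  if (use_x && use_y) {
    r <- suppressWarnings(stats::cor(vx, vy))
    if (is.finite(r) && abs(r) > 1 - 1e-10) {
      X <- cbind(1, vx)
      use_y <- FALSE
      dropped <- c(dropped, "y_collinear")
    }
  }
  coeffs <- array(0, dim = c(ny, nx, 2))
  if (ncol(X) > 1) {
    beta <- stats::lm.fit(X, Y)$coefficients
    j <- 2
    if (use_x) { coeffs[, , 1] <- matrix(beta[j, ], ny, nx); j <- j + 1 }
    else dropped <- c(dropped, "x_no_variance")
    if (use_y) coeffs[, , 2] <- matrix(beta[j, ], ny, nx)
    else if (!"y_collinear" %in% dropped)
      dropped <- c(dropped, "y_no_variance")
  } else {
    dropped <- c(dropped, "x_no_variance", "y_no_variance")
  }
  coeffs[!is.finite(coeffs)] <- 0
  attr(coeffs, "dropped_axes") <- dropped
  class(coeffs) <- c("om_motion_coeffs", class(coeffs))
  coeffs
}

#' Subtract the motion-related component from a stack
#'
#' `I0[x,y,t] = I[x,y,t] - alpha[x,y] . v[t]` per pixel and frame.
#'
#' @param stack `ny x nx x nt` array.
#' @param trace `2 x nt` motion trace.
#' @param coeffs `ny x nx x 2` coefficient array.
#' @return motion-corrected stack of the same shape.
#' @export
stabilize <- function(stack, trace, coeffs) {
  d <- dim(stack)
  if (!identical(dim(coeffs)[1:2], d[1:2]) || ncol(trace) != d[3])
    stop("shape mismatch between stack, trace and coefficients",
         call. = FALSE)
  out <- stack
  ax <- coeffs[, , 1]; ay <- coeffs[, , 2]
  for (tt in seq_len(d[3]))
    out[, , tt] <- stack[, , tt] - ax * trace[1, tt] - ay * trace[2, tt]
  out
}

# Frames on which motion coefficients are fitted: pre-stimulus frames of
# every trial, all frames of blank trials (no visual, no optostim).
stabilization_fit_frames <- function(trials, timeline) {
  pre <- seq_len(timeline$stim_onset_frame - 1)
  all_f <- seq_len(timeline$n_frames)
  blank <- !trials$target_present & trials$opto_power_density == 0
  lapply(seq_len(nrow(trials)), function(i) if (blank[i]) all_f else pre)
}

#' Stabilize every trial of a session
#'
#' Estimates a per-trial motion trace, fits session-pooled per-pixel
#' motion coefficients on pre-stimulus and blank-trial frames, and
#' subtracts the motion-related component from every stack.
#'
#' @param session an `om_session` with stacks.
#' @param per_trial fit coefficients per trial instead of pooled across
#'   the session (the pooled fit is the default; it is more stable).
#' @return the session with corrected stacks, `$motion$traces` and
#'   `$motion$coeffs` attached, and `"stabilize"` appended to `$stages`.
#' @export
stabilize_session <- function(session, per_trial = FALSE) {
  stopifnot(inherits(session, "om_session"), !is.null(session$stacks))
  traces <- lapply(session$stacks, estimate_motion)
  ff <- stabilization_fit_frames(session$trials, session$config$timeline)
  if (per_trial) {
    coeffs <- lapply(seq_along(session$stacks), function(i)
      fit_motion_coefficients(session$stacks[i], traces[i], ff[i]))
    session$stacks <- lapply(seq_along(session$stacks), function(i)
      stabilize(session$stacks[[i]], traces[[i]], coeffs[[i]]))
    session$motion <- list(traces = traces, coeffs = coeffs,
                           mode = "per_trial")
  } else {
    coeffs <- fit_motion_coefficients(session$stacks, traces, ff)
    session$stacks <- lapply(seq_along(session$stacks), function(i)
      stabilize(session$stacks[[i]], traces[[i]], coeffs))
    session$motion <- list(traces = traces, coeffs = coeffs,
                           mode = "session_pooled")
  }
  names(session$stacks) <- as.character(session$trials$trial_id)
  session$stages <- c(session$stages, "stabilize")
  session
}

#' Spatially bin (downsample) a stack
#'
#' Averages non-overlapping `factor x factor` pixel blocks, the binning
#' step of the standard preprocessing chain. `factor = 1` is the identity.
#'
#' @param stack `ny x nx x nt` array; `ny`, `nx` divisible by `factor`.
#' @param factor integer binning factor.
#' @return binned stack.
#' @export
downsample_stack <- function(stack, factor = 1L) {
  factor <- as.integer(factor)
  if (factor == 1L) return(stack)
  d <- dim(stack)
  if (d[1] %% factor || d[2] %% factor)
    stop("image size not divisible by binning factor", call. = FALSE)
  ny <- d[1] %/% factor; nx <- d[2] %/% factor
  out <- array(0, c(ny, nx, d[3]))
  for (tt in seq_len(d[3])) {
    m <- stack[, , tt]
    m <- rowsum(m, rep(seq_len(ny), each = factor))
    m <- t(rowsum(t(m), rep(seq_len(nx), each = factor)))
    out[, , tt] <- m / factor^2
  }
  out
}
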