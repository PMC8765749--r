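# Contrast-response fitting and the proportional-reduction statistic.

#' Naka-Rushton contrast-response function
#'
#' `Z(c) = Z_max * c^n / (c^n + c50^n)`: a saturating contrast-response
#' law with semisaturation contrast `c50` (where `Z = Z_max / 2`) and
#' exponent `n`.
#'
#' @param c Weber contrast(s), `>= 0`.
#' @param zmax response ceiling.
#' @param n exponent (> 0).
#' @param c50 semisaturation contrast (> 0).
#' @return numeric vector.
#' @export
naka_rushton <- function(c, zmax, n, c50) {
  cn <- c^n
  zmax * cn / (cn + c50^n)
}

#' Fit the Naka-Rushton function by weighted least squares
#'
#' Minimizes `sum_c w_c (z_c - Z(c))^2` over `(Z_max, n, c50)`. `Z_max`
#' is profiled out in closed form (it enters linearly given `n` and
#' `c50`), and the remaining 2-D problem is solved by box-constrained
#' quasi-Newton from a deterministic multi-start grid (log-spaced `c50`
#' crossed with a spread of exponents, >= 5 starts), keeping the
#' best-RSS solution. The procedure is deterministic.
#'
#' @param contrasts distinct contrast levels (>= 3, ideally including a
#'   near-zero level).
#' @param z_means mean z-scored response per contrast.
#' @param weights per-contrast weights, typically trial counts.
#' @param n_bounds,c50_bounds box constraints on the exponent and
#'   semisaturation contrast.
#' @return an `om_nrfit` list: `zmax`, `n`, `c50`, `rss`, `weights`,
#'   `flat` (TRUE when all `z_means <= 0` and the flat `Z_max = 0` fit is
#'   returned).
#' @export
fit_naka_rushton <- function(contrasts, z_means, weights = NULL,
                             n_bounds = c(0.2, 8),
                             c50_bounds = NULL) {
  stopifnot(length(contrasts) == length(z_means),
            length(unique(contrasts)) >= 3)
  if (is.null(weights)) weights <- rep(1, length(contrasts))
  cmax <- max(contrasts)
  if (is.null(c50_bounds)) c50_bounds <- c(cmax * 1e-3, cmax * 3)
  if (all(z_means <= 0)) {
    return(structure(list(zmax = 0, n = 1, c50 = c50_bounds[2],
                          rss = sum(weights * z_means^2),
                          weights = weights, flat = TRUE),
                     class = "om_nrfit"))
  }
  obj <- function(p) {
    n <- exp(p[1]); c50 <- exp(p[2])
    g <- contrasts^n / (contrasts^n + c50^n)
    den <- sum(weights * g^2)
    zmax <- if (den > 0) max(sum(weights * g * z_means) / den, 0) else 0
    sum(weights * (z_means - zmax * g)^2)
  }
  starts <- expand.grid(
    n = log(c(0.5, 1, 2, 4)),
    c50 = log(exp(seq(log(c50_bounds[1] * 10), log(c50_bounds[2] / 1.5),
                      length.out = 4))))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(stats::optim(as.numeric(starts[i, ]), obj,
                            method = "L-BFGS-B",
                            lower = log(c(n_bounds[1], c50_bounds[1])),
                            upper = log(c(n_bounds[2], c50_bounds[2]))),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("Naka-Rushton fit failed from all starts",
                          call. = FALSE)
  n <- exp(best$par[1]); c50 <- exp(best$par[2])
  g <- contrasts^n / (contrasts^n + c50^n)
  zmax <- max(sum(weights * g * z_means) / sum(weights * g^2), 0)
  structure(list(zmax = zmax, n = n, c50 = c50, rss = best$value,
                 weights = weights, flat = FALSE),
            class = "om_nrfit")
}

#' Subtract the optostim-only baseline from combined responses
#'
#' The visual contribution to the simultaneous visual + optostim response
#' is `Z_optosub(c) = mean Z_optovis(c) - mean Z_optobase`, where
#' `Z_optobase` is the response on optostim-only trials (target absent)
#' at the same power level.
#'
#' @param z_optovis_trials data.frame with columns `contrast` and `z`:
#'   per-trial z-scores of combined visual + optostim trials.
#' @param z_optobase_trials numeric vector of optostim-only z-scores.
#' @return list `z_optosub` (named per contrast), `contrasts`, `n_trials`
#'   per contrast, `baseline_mean`, `baseline_sd`, `n_baseline`.
#' @export
subtract_optostim_baseline <- function(z_optovis_trials,
                                       z_optobase_trials) {
  if (!length(z_optobase_trials))
    stop("no optostim-only baseline trials", call. = FALSE)
  base_mean <- mean(z_optobase_trials)
  agg <- stats::aggregate(z ~ contrast, z_optovis_trials, mean)
  ns <- stats::aggregate(z ~ contrast, z_optovis_trials, length)
  list(z_optosub = stats::setNames(agg$z - base_mean,
                                   as.character(agg$contrast)),
       contrasts = agg$contrast, n_trials = ns$z,
       baseline_mean = base_mean,
       baseline_sd = stats::sd(z_optobase_trials),
       n_baseline = length(z_optobase_trials))
}

#' Proportional reduction of the visual-evoked response under optostim
#'
#' Finds the `rho` that best explains the baseline-subtracted combined
#' responses as a scaled copy of the visual-only responses, in the
#' weighted least-squares sense:
#' `rho = argmin sum_c w_c (Z_optosub(c) - (1 - rho) Z_vis(c))^2`,
#' with the closed form
#' `rho = 1 - sum(w Z_vis Z_optosub) / sum(w Z_vis^2)`.
#'
#' The estimate is reported unclipped; values outside `[0, 1]` set the
#' `out_of_range` flag rather than being truncated (clipping would bias
#' the bootstrap distribution).
#'
#' @param z_vis_means visual-only mean z per contrast.
#' @param z_optosub_means baseline-subtracted combined mean z per
#'   contrast (matched contrast levels).
#' @param weights per-contrast weights (default trial counts = equal).
#' @return an `om_reduction` list: `rho`, `out_of_range`, and the inputs.
#' @export
compute_reduction <- function(z_vis_means, z_optosub_means,
                              weights = NULL) {
  stopifnot(length(z_vis_means) == length(z_optosub_means))
  if (is.null(weights)) weights <- rep(1, length(z_vis_means))
  den <- sum(weights * z_vis_means^2)
  if (den == 0)
    stop("sum(w * Z_vis^2) is zero; rho undefined", call. = FALSE)
  rho <- 1 - sum(weights * z_vis_means * z_optosub_means) / den
  structure(list(rho = rho, out_of_range = (rho < 0 || rho > 1),
                 z_vis = z_vis_means, z_optosub = z_optosub_means,
                 weights = weights),
            class = "om_reduction")
}

# Per-contrast visual-only means (target-present, no optostim).
vis_condition_means <- function(responses) {
  vis <- responses[responses$opto_power_density == 0 &
                     responses$target_present, , drop = FALSE]
  agg <- stats::aggregate(z ~ target_contrast, vis, mean)
  ns <- stats::aggregate(z ~ target_contrast, vis, length)
  list(contrasts = agg$target_contrast, z = agg$z, n = ns$z)
}

#' Neural reduction analysis of a response table
#'
#' For each optostim power level: subtracts the optostim-only baseline,
#' matches contrast levels against the visual-only block, and computes
#' the proportional reduction `rho_physiology` with trial-count weights
#' (equal weights behind `weight_by_trials = FALSE`).
#'
#' @param responses the `$responses` table of an extracted session (or
#'   any data.frame with the same columns, e.g. pooled over sessions).
#' @param weight_by_trials weight contrasts by trial counts (default) or
#'   equally.
#' @return named list (one entry per power level) of `om_reduction`
#'   objects augmented with `baseline_mean`, `baseline_sd`, `contrasts`,
#'   and Naka-Rushton fits of the visual-only and subtracted curves.
#' @export
analyze_reduction <- function(responses, weight_by_trials = TRUE) {
  vis <- vis_condition_means(responses)
  powers <- sort(unique(
    responses$opto_power_density[responses$opto_power_density > 0]))
  if (!length(powers)) stop("no optostim trials", call. = FALSE)
  out <- list()
  for (p in powers) {
    sel <- responses$opto_power_density == p
    ovis <- responses[sel & responses$target_present, , drop = FALSE]
    obase <- responses$z[sel & !responses$target_present]
    sub <- subtract_optostim_baseline(
      data.frame(contrast = ovis$target_contrast, z = ovis$z), obase)
    common <- intersect(vis$contrasts, sub$contrasts)
    if (!length(common))
      stop("no matched contrast levels between blocks", call. = FALSE)
    iv <- match(common, vis$contrasts); io <- match(common, sub$contrasts)
    w <- if (weight_by_trials) pmin(vis$n[iv], sub$n_trials[io])
    else rep(1, length(common))
    red <- compute_reduction(vis$z[iv], sub$z_optosub[io], w)
    red$contrasts <- common
    red$baseline_mean <- sub$baseline_mean
    red$baseline_sd <- sub$baseline_sd
    red$nr_vis <- if (length(vis$contrasts) >= 3)
      fit_naka_rushton(vis$contrasts, vis$z, vis$n) else NULL
    red$nr_optosub <- if (length(sub$contrasts) >= 3)
      fit_naka_rushton(sub$contrasts, as.numeric(sub$z_optosub),
                       sub$n_trials) else NULL
    out[[as.character(p)]] <- red
  }
  out
}

#' Bootstrap inference for the neural reduction
#'
#' Resamples trials with replacement within each stimulus condition
#' (contrast level x optostim level), recomputes `rho_physiology` per
#' replicate (optionally also the Naka-Rushton fits), and reports the SD
#' of the replicates as the error bar. The p-value against the null of no
#' reduction (`rho = 0`, one-sided toward reduction) is the proportion of
#' replicates agreeing with the null, Bonferroni-adjusted across power
#' levels.
#'
#' @param responses response table as in [analyze_reduction()].
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param weight_by_trials as in [analyze_reduction()].
#' @param refit_naka also refit Naka-Rushton curves per replicate and
#'   report parameter SDs.
#' @param session optional extracted `om_session`. When supplied, each
#'   replicate re-runs the detrend -> window-summary -> z-score tail of
#'   the analysis on the resampled trials (from the stored pre-detrend
#'   ROI time courses) instead of resampling the final z-table. This is
#'   the fuller reading of "recalculated on each resample": the
#'   per-condition detrend parameters are themselves data-dependent, and
#'   resampling only the final z-scores understates their contribution.
#' @return named list per power level: `rho`, `rho_sd`, `p_value`
#'   (Bonferroni-adjusted), `rho_boot` (replicates), and optional
#'   Naka-Rushton parameter SDs.
#' @export
bootstrap_neural <- function(responses, n_boot = 1000, seed = 1L,
                             weight_by_trials = TRUE,
                             refit_naka = FALSE, session = NULL) {
  if (n_boot < 2) stop("n_boot must be >= 2", call. = FALSE)
  if (!is.null(session))
    return(bootstrap_neural_timecourses(session, n_boot, seed,
                                        weight_by_trials))
  point <- analyze_reduction(responses, weight_by_trials)
  cond <- interaction(responses$condition_id, drop = TRUE)
  idx_by_cond <- split(seq_len(nrow(responses)), cond)
  powers <- names(point)
  boot <- matrix(NA_real_, n_boot, length(powers),
                 dimnames = list(NULL, powers))
  nr_boot <- if (refit_naka)
    lapply(powers, function(p) matrix(NA_real_, n_boot, 3)) else NULL
  if (refit_naka) names(nr_boot) <- powers
  withr_seed(seed, {
    for (b in seq_len(n_boot)) {
      take <- unlist(lapply(idx_by_cond, function(ii)
        ii[sample.int(length(ii), replace = TRUE)]), use.names = FALSE)
      rb <- try(analyze_reduction(responses[take, , drop = FALSE],
                                  weight_by_trials), silent = TRUE)
      if (inherits(rb, "try-error")) next
      for (p in powers) {
        boot[b, p] <- rb[[p]]$rho
        if (refit_naka && !is.null(rb[[p]]$nr_vis))
          nr_boot[[p]][b, ] <- c(rb[[p]]$nr_vis$zmax, rb[[p]]$nr_vis$n,
                                 rb[[p]]$nr_vis$c50)
      }
    }
  })
  k <- length(powers)
  out <- list()
  for (p in powers) {
    reps <- boot[, p][is.finite(boot[, p])]
    p_raw <- mean(reps <= 0)
    out[[p]] <- list(
      rho = point[[p]]$rho,
      rho_sd = stats::sd(reps),
      p_value = min(1, p_raw * k),
      rho_boot = reps,
      baseline_mean = point[[p]]$baseline_mean,
      baseline_sd = point[[p]]$baseline_sd)
    if (refit_naka)
      out[[p]]$nr_vis_sd <- apply(nr_boot[[p]], 2, stats::sd, na.rm = TRUE)
  }
  out
}

# Timecourse-level bootstrap: resample trials within stimulus condition
# and re-run detrend -> window summary -> z-score -> reduction per
# replicate, so the data-dependence of the detrend parameters and of
# sigma_blank is reflected in the replicate spread. The ROI and the
# upstream stack-level fits (stabilization, heartbeat) stay fixed.
bootstrap_neural_timecourses <- function(session, n_boot, seed,
                                         weight_by_trials = TRUE) {
  stopifnot(!is.null(session$timecourses_raw), !is.null(session$responses))
  tl <- session$config$timeline
  trials <- session$trials
  tc <- session$timecourses_raw
  valid <- session$valid_mask
  pre <- seq_len(tl$stim_onset_frame - 1)   # as in extract_session
  win <- session$config$response_window_ms
  wf <- window_frames_of(tl, win)

  point <- analyze_reduction(session$responses, weight_by_trials)
  powers <- names(point)
  idx_by_cond <- split(seq_len(nrow(trials)), trials$condition_id)
  boot <- matrix(NA_real_, n_boot, length(powers),
                 dimnames = list(NULL, powers))
  withr_seed(seed, {
    for (b in seq_len(n_boot)) {
      take <- unlist(lapply(idx_by_cond, function(ii)
        ii[sample.int(length(ii), replace = TRUE)]), use.names = FALSE)
      det <- detrend(tc[take, , drop = FALSE],
                     trials$condition_id[take], pre, tl$frame_start_ms,
                     valid_mask = valid[take, , drop = FALSE])
      R <- rowMeans(det$timecourses[, wf, drop = FALSE])
      blank <- !trials$target_present[take] &
        trials$opto_power_density[take] == 0
      zs <- try(zscore_responses(R, blank), silent = TRUE)
      if (inherits(zs, "try-error")) next
      resp <- data.frame(
        trial_id = trials$trial_id[take],
        condition_id = trials$condition_id[take],
        target_present = trials$target_present[take],
        target_contrast = trials$target_contrast[take],
        opto_power_density = trials$opto_power_density[take],
        z = zs$z)
      rb <- try(analyze_reduction(resp, weight_by_trials), silent = TRUE)
      if (inherits(rb, "try-error")) next
      for (p in powers) boot[b, p] <- rb[[p]]$rho
    }
  })
  k <- length(powers)
  out <- list()
  for (p in powers) {
    reps <- boot[, p][is.finite(boot[, p])]
    out[[p]] <- list(rho = point[[p]]$rho, rho_sd = stats::sd(reps),
                     p_value = min(1, mean(reps <= 0) * k),
                     rho_boot = reps,
                     baseline_mean = point[[p]]$baseline_mean,
                     baseline_sd = point[[p]]$baseline_sd)
  }
  out
}
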