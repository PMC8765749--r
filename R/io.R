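# Session serialization.
#
# A session directory contains plain-text artifacts:
#   config.json        geometry, timeline, design and analysis constants
#   trials.csv         one row per trial (the TrialRecord columns)
#   ground_truth.json  generator parameters (synthetic sessions only)
#   stacks/trial_<id>.csv   one CSV per trial: n_frames rows, each row a
#                           frame flattened column-major (y fastest)
# An alternative single-file RDS container is available for speed; the
# text format is the interchange format.

trial_columns <- c("trial_id", "block_id", "condition_id",
                   "target_present", "target_contrast", "block_contrast",
                   "opto_power_density", "heart_rate", "choice",
                   "outcome", "saccade_time_ms")

config_to_list <- function(config) {
  tl <- config$timeline
  list(
    geometry = config$geometry,
    timeline = tl[c("frame_rate_hz", "n_frames", "cue_time_ms",
                    "target_onset_ms", "optostim_onset_ms",
                    "target_max_duration_ms", "optostim_max_duration_ms",
                    "pulse_width_ms", "pulse_period_ms")],
    stimulus = unclass(config$stimulus),
    contrasts = config$contrasts, opto_powers = config$opto_powers,
    n_per_cond = config$n_per_cond,
    target_present_frac = config$target_present_frac,
    hr_mean = config$hr_mean, hr_sd = config$hr_sd,
    saccade_median_ms = config$saccade_median_ms,
    saccade_sdlog = config$saccade_sdlog,
    roi_mm = config$roi_mm,
    response_window_ms = config$response_window_ms,
    n_boot = config$n_boot,
    rescale_lo = config$rescale_lo, rescale_slope = config$rescale_slope)
}

config_from_list <- function(x) {
  tl <- do.call(build_timeline,
                c(x$timeline,
                  list(optostim_delay_ms = x$timeline$optostim_onset_ms -
                         x$timeline$target_onset_ms)))
  st <- stimulus_spec(
    weber_contrast = x$stimulus$weber_contrast,
    background_luminance = x$stimulus$background_luminance,
    target_fwhm_deg = x$stimulus$target_fwhm_deg,
    site_centers_px = if (is.matrix(x$stimulus$site_centers_px))
      asplit(x$stimulus$site_centers_px, 1)   # json array-of-arrays
    else lapply(x$stimulus$site_centers_px, as.numeric),
    site_fwhm_px = x$stimulus$site_fwhm_px)
  session_config(
    nx = x$geometry$nx, ny = x$geometry$ny,
    mm_per_px = x$geometry$mm_per_px,
    timeline = tl, stimulus = st,
    contrasts = as.numeric(x$contrasts),
    opto_powers = as.numeric(x$opto_powers),
    n_per_cond = x$n_per_cond,
    target_present_frac = x$target_present_frac,
    hr_mean = x$hr_mean, hr_sd = x$hr_sd,
    saccade_median_ms = x$saccade_median_ms,
    saccade_sdlog = x$saccade_sdlog,
    roi_mm = x$roi_mm,
    response_window_ms = as.numeric(x$response_window_ms),
    n_boot = x$n_boot)
}

#' Write a session to disk
#'
#' @param session an `om_session`.
#' @param dir output directory (created if needed).
#' @param format `"csv"` (plain-text, interchange) or `"rds"` (single
#'   binary file, fast).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, format = c("csv", "rds")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "rds") {
    saveRDS(session, file.path(dir, "session.rds"))
    return(invisible(dir))
  }
  jsonlite::write_json(config_to_list(session$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  data.table::fwrite(session$trials[, trial_columns],
                     file.path(dir, "trials.csv"))
  if (!is.null(session$ground_truth)) {
    gt <- session$ground_truth
    gt$drift_ms <- NULL   # session-internal; re-drawn from the seed
    jsonlite::write_json(unclass(gt), file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(session$stacks)) {
    sdir <- file.path(dir, "stacks")
    dir.create(sdir, showWarnings = FALSE)
    for (id in names(session$stacks)) {
      s <- session$stacks[[id]]
      m <- t(matrix(s, prod(dim(s)[1:2]), dim(s)[3]))
      data.table::fwrite(data.table::as.data.table(m),
                         file.path(sdir, sprintf("trial_%s.csv", id)),
                         col.names = FALSE)
    }
  }
  invisible(dir)
}

#' Read a session from disk
#'
#' Validates the trial table schema (missing columns are reported by
#' name) and the frame count of every stack against the configuration.
#'
#' @param dir session directory written by [write_session()].
#' @return an `om_session` (without ground-truth sidecars; those live in
#'   memory or in `ground_truth.json`).
#' @export
read_session <- function(dir) {
  rds <- file.path(dir, "session.rds")
  if (file.exists(rds)) return(readRDS(rds))
  cfg_path <- file.path(dir, "config.json")
  if (!file.exists(cfg_path)) stop("missing config.json in ", dir,
                                   call. = FALSE)
  config <- config_from_list(jsonlite::read_json(cfg_path,
                                                 simplifyVector = TRUE))
  trials <- as.data.frame(data.table::fread(file.path(dir, "trials.csv")))
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols))
    stop("trials.csv missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- NULL
  if (file.exists(gt_path)) {
    raw <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    raw$psych_params <- lapply(raw$psych_params, as.list)
    raw$opto_amplitude <- as.list(raw$opto_amplitude)
    gt <- do.call(ground_truth, raw)
  }
  stacks <- NULL
  sdir <- file.path(dir, "stacks")
  if (dir.exists(sdir)) {
    g <- config$geometry; nt <- config$timeline$n_frames
    stacks <- lapply(as.character(trials$trial_id), function(id) {
      f <- file.path(sdir, sprintf("trial_%s.csv", id))
      if (!file.exists(f)) stop("missing stack for trial ", id,
                                call. = FALSE)
      m <- as.matrix(data.table::fread(f, header = FALSE))
      if (nrow(m) != nt || ncol(m) != g$ny * g$nx)
        stop(sprintf(
          "trial %s: stack is %d frames x %d px, config says %d x %d",
          id, nrow(m), ncol(m), nt, g$ny * g$nx), call. = FALSE)
      array(t(m), dim = c(g$ny, g$nx, nt))
    })
    names(stacks) <- as.character(trials$trial_id)
  }
  structure(list(stacks = stacks, trials = trials, config = config,
                 ground_truth = gt, maps = NULL, sidecars = NULL,
                 seed = NA_integer_, stages = character(0)),
            class = "om_session")
}
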