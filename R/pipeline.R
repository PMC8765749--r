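# End-to-end pipeline and command-line entry point.

#' Preprocess a session
#'
#' Runs the fixed preprocessing order: stabilize -> downsample -> dF/F ->
#' heartbeat removal -> pre-stimulus anchoring / detrend + extraction.
#' The order is part of the method and is not configurable.
#'
#' @param session an `om_session` with raw stacks.
#' @param downsample_factor spatial binning factor (default 1).
#' @param stages subset of `c("stabilize", "heartbeat")` to apply; dF/F
#'   and extraction always run. Used by tests to isolate stages.
#' @return the session with `$responses` attached.
#' @export
preprocess_session <- function(session, downsample_factor = 1L,
                               stages = c("stabilize", "heartbeat")) {
  if ("stabilize" %in% stages) session <- stabilize_session(session)
  if (downsample_factor > 1L) {
    session$stacks <- lapply(session$stacks, downsample_stack,
                             factor = downsample_factor)
    g <- session$config$geometry
    session$config$geometry$nx <- g$nx %/% downsample_factor
    session$config$geometry$ny <- g$ny %/% downsample_factor
    session$config$geometry$mm_per_px <- g$mm_per_px * downsample_factor
    session$stages <- c(session$stages, "downsample")
  }
  session <- dff_session(session)
  if ("heartbeat" %in% stages) session <- heartbeat_session(session)
  extract_session(session)
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a session, preprocesses it, and runs the neural
#' reduction analysis and the behavioral psychometric analysis, with
#' bootstrap inference on both. Returns a run report that records the
#' seed and configuration alongside every fitted parameter, plus curve
#' tables for plotting.
#'
#' @param config an `om_config` (a session is generated from it) or an
#'   existing `om_session`.
#' @param seed integer seed for generation and bootstrap resampling.
#' @param out_dir optional directory: the report is written as
#'   `report.json` and the curve tables as CSVs.
#' @param n_boot bootstrap resamples; defaults to the config's `n_boot`.
#' @return an `om_report` list: `neural` (per power: rho, SD, p-value,
#'   baselines), `behavior` (per power: alpha/beta/delta, SDs, p-values,
#'   rho_behavior), `psych_fit`, `roi`, `seed`, `config`.
#' @export
run_pipeline <- function(config, seed = 1L, out_dir = NULL,
                         n_boot = NULL) {
  session <- if (inherits(config, "om_session")) config
  else generate_session(config, seed = seed)
  cfg <- session$config
  n_boot <- n_boot %||% cfg$n_boot

  stage <- "preprocess"
  report <- list(seed = seed, n_trials = nrow(session$trials))
  res <- try({
    session <- preprocess_session(session)
    stage <- "analyze-neural"
    neural <- bootstrap_neural(session$responses, n_boot = n_boot,
                               seed = child_seed(seed, 7001))
    stage <- "analyze-behavior"
    behavior <- bootstrap_behavior(session$trials, n_boot = n_boot,
                                   seed = child_seed(seed, 7002))
    NULL
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stop(sprintf("pipeline failed at stage `%s`: %s", stage,
                 attr(res, "condition")$message), call. = FALSE)

  vis <- vis_condition_means(session$responses)
  nr_vis <- if (length(vis$contrasts) >= 3)
    fit_naka_rushton(vis$contrasts, vis$z, vis$n) else NULL

  report$roi <- unclass(session$roi)
  report$sigma_blank <- session$zscore$sd_blank
  report$neural <- lapply(neural, function(x)
    x[c("rho", "rho_sd", "p_value", "baseline_mean", "baseline_sd")])
  report$behavior <- lapply(behavior, function(x) list(
    alpha_vis = x$fit$blocks$visual$alpha,
    alpha_opto = x$fit$blocks$opto$alpha,
    beta = x$fit$beta,
    delta_vis = x$fit$blocks$visual$delta,
    delta_opto = x$fit$blocks$opto$delta,
    rho_behavior = x$rho_behavior,
    rho_behavior_sd = x$rho_behavior_sd,
    alpha_sd_normalized = as.list(x$alpha_sd_normalized),
    delta_sd = as.list(x$delta_sd),
    p_threshold = x$p_threshold, p_criterion = x$p_criterion))
  report$naka_rushton_visual <- if (!is.null(nr_vis))
    nr_vis[c("zmax", "n", "c50")] else NULL
  report$stages <- session$stages
  report$config <- config_to_list(cfg)

  # figure-equivalent curve tables
  curves <- list()
  if (!is.null(nr_vis)) {
    cg <- seq(0, max(vis$contrasts), length.out = 50)
    curves$contrast_response <- data.frame(
      contrast = cg,
      z = naka_rushton(cg, nr_vis$zmax, nr_vis$n, nr_vis$c50))
  }
  for (p in names(behavior)) {
    f <- behavior[[p]]$fit
    cg <- seq(0, max(session$trials$block_contrast), length.out = 50)
    curves[[paste0("psychometric_", p)]] <- data.frame(
      contrast = cg,
      pc_visual = bias_corrected_percent_correct(f, cg, "visual"),
      pc_opto = bias_corrected_percent_correct(f, cg, "opto"))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (nm in names(curves))
      data.table::fwrite(curves[[nm]],
                         file.path(out_dir, paste0(nm, ".csv")))
    data.table::fwrite(session$responses,
                       file.path(out_dir, "responses.csv"))
  }
  structure(c(report, list(curves = curves, session = session,
                           neural_full = neural,
                           behavior_full = behavior)),
            class = "om_report")
}

#' @export
print.om_report <- function(x, ...) {
  cat("<om_report>\n")
  for (p in names(x$neural))
    cat(sprintf(
      "  neural PD %s: rho = %.3f +- %.3f (p = %.3g)\n", p,
      x$neural[[p]]$rho, x$neural[[p]]$rho_sd, x$neural[[p]]$p_value))
  for (p in names(x$behavior)) {
    b <- x$behavior[[p]]
    cat(sprintf(
      "  behavior PD %s: rho_behavior = %.3f +- %.3f (p = %.3g)\n", p,
      b$rho_behavior, b$rho_behavior_sd, b$p_threshold))
  }
  invisible(x)
}

#' Command-line interface
#'
#' Verbs: `simulate` (write a synthetic session), `preprocess` (stacks ->
#' response table), `analyze-neural`, `analyze-behavior`, and `run`
#' (end-to-end). Arguments are `--key value` pairs; see the README.
#'
#' @param args character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return exit status (0 on success), invisibly.
#' @export
optomask_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: optomask <simulate|preprocess|analyze-neural|",
        "analyze-behavior|run> [--seed N] [--out DIR] [--in DIR]",
        "[--n-boot N] [--rho X] [--n-per-cond N]\n", sep = "")
    return(invisible(1L))
  }
  verb <- args[1]
  opt <- list(seed = 1L, out = "optomask_out", `in` = NULL,
              `n-boot` = NULL, rho = 0.5, `n-per-cond` = 20,
              stage = "all")
  i <- 2
  while (i < length(args) + 1 && startsWith(args[i] %||% "", "--")) {
    key <- sub("^--", "", args[i])
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  seed <- as.integer(opt$seed)
  cfg <- session_config(
    n_per_cond = as.integer(opt$`n-per-cond`),
    ground_truth = ground_truth(rho_true = as.numeric(opt$rho)))
  status <- 0L
  dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
  if (verb == "simulate") {
    s <- generate_session(cfg, seed = seed)
    write_session(s, opt$out)
    cat("wrote session to", opt$out, "\n")
  } else if (verb == "preprocess") {
    s <- read_session(opt$`in`)
    s <- preprocess_session(s)
    data.table::fwrite(s$responses, file.path(opt$out, "responses.csv"))
    cat("wrote", file.path(opt$out, "responses.csv"), "\n")
  } else if (verb == "analyze-neural") {
    resp <- as.data.frame(data.table::fread(
      file.path(opt$`in`, "responses.csv")))
    nb <- as.integer(opt$`n-boot` %||% 1000)
    res <- bootstrap_neural(resp, n_boot = nb, seed = seed)
    jsonlite::write_json(lapply(res, function(x)
      x[c("rho", "rho_sd", "p_value")]),
      file.path(opt$out, "neural.json"), auto_unbox = TRUE, digits = NA)
    cat("wrote", file.path(opt$out, "neural.json"), "\n")
  } else if (verb == "analyze-behavior") {
    tab <- as.data.frame(data.table::fread(
      file.path(opt$`in`, "trials.csv")))
    nb <- as.integer(opt$`n-boot` %||% 1000)
    res <- bootstrap_behavior(tab, n_boot = nb, seed = seed)
    jsonlite::write_json(lapply(res, function(x) list(
      rho_behavior = x$rho_behavior, rho_behavior_sd = x$rho_behavior_sd,
      p_threshold = x$p_threshold)),
      file.path(opt$out, "behavior.json"), auto_unbox = TRUE, digits = NA)
    cat("wrote", file.path(opt$out, "behavior.json"), "\n")
  } else if (verb == "run") {
    nb <- as.integer(opt$`n-boot` %||% 200)
    rep <- run_pipeline(cfg, seed = seed, out_dir = opt$out, n_boot = nb)
    print(rep)
  } else {
    cat("unknown verb:", verb, "\n")
    status <- 1L
  }
  invisible(status)
}
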