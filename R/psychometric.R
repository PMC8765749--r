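#' Signal-detection psychometric model
#'
#' The detection task is modeled with an equal-variance signal-detection
#' observer whose sensitivity grows as a power function of target contrast,
#' `d'(c) = (c / alpha)^beta`, so that `alpha` is the detection threshold
#' (the contrast at which d' = 1) and `beta` the steepness of the
#' psychometric curve. With criterion bias `delta` (in d' units; positive =
#' bias toward reporting the target absent) the predicted proportions are
#'
#'   P(hit) = Phi(d'(c)/2 - delta),   P(cr) = Phi(d'(c)/2 + delta),
#'
#' where `Phi` is the standard normal CDF. At `c = alpha` and `delta = 0`
#' both equal `Phi(0.5)`, i.e. about 69% correct: the threshold convention.
#'
#' @param contrast Weber contrast(s), `>= 0`. On target-absent trials the
#'   relevant contrast for P(cr) is the contrast of the block the trial was
#'   run in (the blocked design holds target contrast constant per block).
#' @param alpha detection threshold contrast, `> 0`.
#' @param beta psychometric steepness, `> 0`.
#' @param delta criterion bias in d' units.
#' @return a list with numeric vectors `p_hit` and `p_cr`.
#' @export
#' @examples
#' psychometric_probability(0.05, alpha = 0.05, beta = 1.5, delta = 0)
psychometric_probability <- function(contrast, alpha, beta, delta = 0) {
  if (any(alpha <= 0)) stop("alpha must be > 0", call. = FALSE)
  if (any(beta <= 0)) stop("beta must be > 0", call. = FALSE)
  if (any(contrast < 0)) stop("contrast must be >= 0", call. = FALSE)
  dprime <- (contrast / alpha)^beta
  list(p_hit = stats::pnorm(dprime / 2 - delta),
       p_cr  = stats::pnorm(dprime / 2 + delta))
}

#' Bias-corrected percent correct
#'
#' Converts a fitted (or specified) psychometric model to the percent
#' correct an unbiased observer (criterion `delta = 0`) would achieve:
#' `100 * Phi((c/alpha)^beta / 2)`. This is the quantity plotted as
#' "bias-corrected % correct"; at `c = alpha` it is ~69%.
#'
#' @param fit either an `om_psychfit` (see [fit_psychometric_joint()]), or a
#'   list/vector with elements `alpha` and `beta`.
#' @param contrast Weber contrast(s) at which to evaluate.
#' @param block for joint fits, which block's threshold to use
#'   (`"visual"` or `"opto"`).
#' @return percent correct values in `[50, 100)`.
#' @export
bias_corrected_percent_correct <- function(fit, contrast, block = "visual") {
  par <- psych_par(fit, block)
  dprime <- (contrast / par$alpha)^par$beta
  100 * stats::pnorm(dprime / 2)
}

# Pull (alpha, beta, delta) out of a fit object or a bare list.
psych_par <- function(fit, block = "visual") {
  if (inherits(fit, "om_psychfit")) {
    b <- fit$blocks[[match.arg(block, names(fit$blocks))]]
    list(alpha = b$alpha, beta = fit$beta, delta = b$delta)
  } else {
    list(alpha = fit[["alpha"]], beta = fit[["beta"]],
         delta = fit[["delta"]] %||% 0)
  }
}

#' Simulate behavioral choices from the psychometric model
#'
#' Draws an outcome for every trial of a trial table from the
#' signal-detection model, independently per trial: on target-present
#' trials a hit with probability `P(hit)`, otherwise a miss; on
#' target-absent trials a correct rejection with probability `P(cr)`,
#' otherwise a false alarm. Absent trials use the block contrast
#' (`block_contrast` column) in the model, as in the blocked task design.
#'
#' @param trial_table data.frame with columns `block_id`, `target_present`
#'   (logical), `block_contrast` (Weber contrast of the trial's condition).
#' @param psych_params named list mapping each `block_id` to a list with
#'   `alpha`, `beta`, `delta`.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return the trial table with columns `choice` (`"saccade"`/`"stay"`) and
#'   `outcome` (`"hit"`, `"miss"`, `"false_alarm"`, `"correct_rejection"`)
#'   filled in.
#' @export
simulate_choices <- function(trial_table, psych_params, seed = 1L) {
  needed <- c("block_id", "target_present", "block_contrast")
  miss <- setdiff(needed, names(trial_table))
  if (length(miss))
    stop("trial_table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- nrow(trial_table)
  p_correct <- numeric(n)
  for (blk in unique(trial_table$block_id)) {
    par <- psych_params[[blk]]
    if (is.null(par))
      stop("no psychometric parameters for block ", blk, call. = FALSE)
    if (par$alpha <= 0 || par$beta <= 0)
      stop("alpha and beta must be > 0", call. = FALSE)
    idx <- which(trial_table$block_id == blk)
    pr <- psychometric_probability(trial_table$block_contrast[idx],
                                   par$alpha, par$beta, par$delta %||% 0)
    p_correct[idx] <- ifelse(trial_table$target_present[idx],
                             pr$p_hit, pr$p_cr)
  }
  withr_seed(seed, {
    correct <- stats::runif(n) < p_correct
  })
  present <- trial_table$target_present
  trial_table$choice <- ifelse(present == correct, "saccade", "stay")
  trial_table$outcome <- ifelse(
    present, ifelse(correct, "hit", "miss"),
    ifelse(correct, "correct_rejection", "false_alarm"))
  trial_table
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Deterministic per-trial child seed from a session seed: a fixed counter
# scheme so single trials can be re-rendered in isolation.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}
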