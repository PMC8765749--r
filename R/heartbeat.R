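# Heartbeat-artifact removal.
#
# Acquisition is triggered on a QRS upstroke of the EKG, so the heartbeat
# artifact is locked to acquisition start but stretches or compresses
# across frames as the heart rate varies from trial to trial. At a given
# pixel and frame index the intensity therefore varies predictably with
# the trial's heart rate. The model is
#   I[x,y,t,k] = S[x,y,t,s(k)] + f[x,y,t](HR[k]),
# with f a fourth-order polynomial of the heart rate with no constant
# term; S (the heart-rate-free stimulus-driven condition response) and the
# polynomial coefficients are estimated simultaneously by least squares,
# and the estimated heart-rate-related component is subtracted out.
#
# Numerics: raw HR^1..HR^4 columns are catastrophically collinear, so HR
# is standardized before building the polynomial, and each polynomial
# column is mean-centered. Centering does not change the model class (the
# constant absorbed by the condition indicators), and it guarantees the
# fitted artifact has exactly zero mean over trials.

#' Fit the joint condition-response + heart-rate polynomial model
#'
#' Per pixel and frame index, solves the linear model with one indicator
#' column per stimulus condition plus four centered polynomial columns of
#' the standardized heart rate, as a single batched least-squares call
#' over all pixels and frames.
#'
#' @param stacks list of `ny x nx x nt` arrays (typically dF/F stacks).
#' @param trial_table data.frame with `condition_id` and `heart_rate`
#'   aligned with `stacks`.
#' @param hr_tol minimum SD of heart rate (beats/min) below which the
#'   model is degenerate and a zero model is returned with a warning.
#' @return list with `model` (an `om_heartbeat_model`: coefficient array
#'   `ny x nx x nt x 4`, `hr_center`, `hr_scale`, `col_center`) and
#'   `condition_means` (named list of fitted `S[x,y,t]` per condition).
#'   Conditions with a single trial are flagged in
#'   `model$single_trial_conditions`.
#' @export
fit_heartbeat_model <- function(stacks, trial_table, hr_tol = 1e-8) {
  stopifnot(length(stacks) == nrow(trial_table))
  if (anyNA(trial_table$heart_rate))
    stop("missing heart_rate for trial(s) ",
         paste(trial_table$trial_id[is.na(trial_table$heart_rate)],
               collapse = ", "), call. = FALSE)
  d <- dim(stacks[[1]])
  ny <- d[1]; nx <- d[2]; nt <- d[3]
  n <- length(stacks)
  hr <- trial_table$heart_rate
  cond <- factor(trial_table$condition_id)
  singles <- names(which(table(cond) == 1))

  hr_center <- mean(hr)
  hr_scale <- stats::sd(hr)
  model_zero <- function() {
    structure(list(coef = array(0, c(ny, nx, nt, 4)),
                   hr_center = hr_center, hr_scale = 1,
                   col_center = rep(0, 4),
                   single_trial_conditions = singles,
                   degenerate = TRUE),
              class = "om_heartbeat_model")
  }
  if (!is.finite(hr_scale) || hr_scale < hr_tol || n < 2) {
    warning("heart-rate variance below tolerance; heartbeat model is a no-op")
    cm <- condition_mean_stacks(stacks, cond)
    return(list(model = model_zero(), condition_means = cm))
  }

  z <- (hr - hr_center) / hr_scale
  P <- cbind(z, z^2, z^3, z^4)
  col_center <- colMeans(P)
  P <- sweep(P, 2, col_center)
  X <- cbind(stats::model.matrix(~ 0 + cond), P)

  Y <- matrix(0, n, ny * nx * nt)
  for (k in seq_len(n)) Y[k, ] <- as.vector(stacks[[k]])
  fit <- stats::lm.fit(X, Y)
  beta <- fit$coefficients
  beta[!is.finite(beta)] <- 0   # minimum-norm convention on rank deficiency

  ncond <- nlevels(cond)
  cm <- lapply(seq_len(ncond), function(j)
    array(beta[j, ], c(ny, nx, nt)))
  names(cm) <- levels(cond)
  coef <- array(t(beta[ncond + 1:4, , drop = FALSE]), c(ny, nx, nt, 4))
  model <- structure(list(coef = coef, hr_center = hr_center,
                          hr_scale = hr_scale, col_center = col_center,
                          single_trial_conditions = singles,
                          degenerate = FALSE),
                     class = "om_heartbeat_model")
  list(model = model, condition_means = cm)
}

condition_mean_stacks <- function(stacks, cond) {
  lapply(stats::setNames(levels(cond), levels(cond)), function(lv) {
    idx <- which(cond == lv)
    Reduce(`+`, stacks[idx]) / length(idx)
  })
}

# The fitted artifact for one heart rate: sum_j coef_j * (z^j - center_j).
heartbeat_artifact <- function(model, heart_rate) {
  z <- (heart_rate - model$hr_center) / model$hr_scale
  basis <- z^(1:4) - model$col_center
  model$coef[, , , 1] * basis[1] + model$coef[, , , 2] * basis[2] +
    model$coef[, , , 3] * basis[3] + model$coef[, , , 4] * basis[4]
}

#' Subtract the fitted heartbeat component from every trial
#'
#' `out[k] = in[k] - f_hat[x,y,t](HR[k])`. Because the polynomial basis is
#' mean-centered over the fitted trials, the subtracted component averages
#' to zero across trials, so condition means are unchanged.
#'
#' @param stacks list of stacks the model was fitted on (or same-geometry
#'   stacks from the same session).
#' @param model an `om_heartbeat_model`.
#' @param trial_table data.frame with `heart_rate` aligned with `stacks`.
#' @return list of cleaned stacks.
#' @export
remove_heartbeat <- function(stacks, model, trial_table) {
  stopifnot(inherits(model, "om_heartbeat_model"),
            length(stacks) == nrow(trial_table))
  bad <- which(!is.finite(trial_table$heart_rate))
  if (length(bad))
    stop("missing heart_rate for trial(s) ",
         paste(trial_table$trial_id[bad], collapse = ", "), call. = FALSE)
  if (model$degenerate) return(stacks)
  out <- vector("list", length(stacks))
  for (k in seq_along(stacks))
    out[[k]] <- stacks[[k]] -
      heartbeat_artifact(model, trial_table$heart_rate[k])
  names(out) <- names(stacks)
  out
}

#' Fit and remove the heartbeat artifact for a session
#'
#' @param session an `om_session` (stacks normally already stabilized and
#'   converted to dF/F).
#' @return the session with cleaned stacks, `$heartbeat` (model and
#'   fitted condition means) attached, and `"heartbeat"` appended to
#'   `$stages`.
#' @export
heartbeat_session <- function(session) {
  stopifnot(inherits(session, "om_session"), !is.null(session$stacks))
  fit <- fit_heartbeat_model(session$stacks, session$trials)
  session$stacks <- remove_heartbeat(session$stacks, fit$model,
                                     session$trials)
  session$heartbeat <- fit
  session$stages <- c(session$stages, "heartbeat")
  session
}
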