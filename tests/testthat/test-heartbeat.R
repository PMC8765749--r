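# Joint condition-response + heart-rate polynomial fitting and removal.

# tiny synthetic instance: n trials of ny x nx x nt stacks with known
# condition means and a known HR-dependent artifact
hb_instance <- function(n = 12, ny = 4, nx = 4, nt = 3, noise = 0,
                        artifact = function(hr) 0, seed = 5) {
  set.seed(seed)
  hr <- rnorm(n, 150, 10)
  cond <- rep(c("a", "b"), length.out = n)
  base <- list(a = array(rnorm(ny * nx * nt), c(ny, nx, nt)),
               b = array(rnorm(ny * nx * nt), c(ny, nx, nt)))
  amp_map <- array(rnorm(ny * nx * nt), c(ny, nx, nt))
  stacks <- lapply(seq_len(n), function(k)
    base[[cond[k]]] + amp_map * artifact(hr[k]) +
      array(rnorm(ny * nx * nt, 0, noise), c(ny, nx, nt)))
  list(stacks = stacks, amp_map = amp_map,
       trials = data.frame(trial_id = seq_len(n), condition_id = cond,
                           heart_rate = hr),
       base = base, hr = hr, cond = cond)
}

test_that("identical heart rates give a zero model and a no-op removal", {
  inst <- hb_instance()
  inst$trials$heart_rate <- rep(150, nrow(inst$trials))
  expect_warning(fit <- fit_heartbeat_model(inst$stacks, inst$trials),
                 "no-op")
  expect_true(all(fit$model$coef == 0))
  out <- remove_heartbeat(inst$stacks, fit$model, inst$trials)
  expect_identical(out, inst$stacks)
})

test_that("a linear-in-HR artifact is recovered exactly without noise", {
  inst <- hb_instance(artifact = function(hr) 0.7 * (hr - 150))
  fit <- fit_heartbeat_model(inst$stacks, inst$trials)
  out <- remove_heartbeat(inst$stacks, fit$model, inst$trials)
  # residual artifact power: compare against the artifact-free stacks
  # (up to the per-condition mean shift absorbed by S)
  for (cd in c("a", "b")) {
    idx <- which(inst$cond == cd)
    for (k in idx) {
      resid <- out[[k]] - Reduce(`+`, out[idx]) / length(idx)
      truth <- inst$stacks[[k]] -
        inst$amp_map * 0.7 * (inst$hr[k] - 150) -
        Reduce(`+`, lapply(idx, function(j)
          inst$stacks[[j]] - inst$amp_map * 0.7 * (inst$hr[j] - 150))) /
        length(idx)
      expect_lt(max(abs(resid - truth)), 1e-8)
    }
  }
})

test_that("joint fit equals the two-step FWL solution to 1e-10", {
  inst <- hb_instance(n = 10, artifact = function(hr)
    1e-3 * (hr - 150)^2 - 0.05 * (hr - 150), noise = 0.2)
  fit <- fit_heartbeat_model(inst$stacks, inst$trials)
  # oracle: per pixel/frame, demean y and the centered polynomial columns
  # within condition, then ordinary least squares on the residuals
  hr <- inst$trials$heart_rate
  z <- (hr - mean(hr)) / sd(hr)
  P <- cbind(z, z^2, z^3, z^4)
  P <- sweep(P, 2, colMeans(P))
  cond <- inst$trials$condition_id
  demean <- function(m) {
    for (cd in unique(cond)) {
      i <- cond == cd
      m[i, ] <- sweep(m[i, , drop = FALSE], 2,
                      colMeans(m[i, , drop = FALSE]))
    }
    m
  }
  Pd <- demean(P)
  for (px in list(c(1, 1, 1), c(3, 2, 2), c(4, 4, 3))) {
    y <- sapply(inst$stacks, function(s) s[px[1], px[2], px[3]])
    beta_two_step <- qr.coef(qr(Pd), demean(matrix(y)))
    expect_lt(max(abs(fit$model$coef[px[1], px[2], px[3], ] -
                        beta_two_step)), 1e-10)
  }
})

test_that("removal is mean-preserving and keeps condition contrasts", {
  inst <- hb_instance(n = 14, artifact = function(hr)
    0.5 * (hr - 150) + 2e-4 * (hr - 150)^3, noise = 0.1)
  fit <- fit_heartbeat_model(inst$stacks, inst$trials)
  out <- remove_heartbeat(inst$stacks, fit$model, inst$trials)
  sub <- Reduce(`+`, lapply(seq_along(out), function(k)
    inst$stacks[[k]] - out[[k]])) / length(out)
  scale <- max(abs(unlist(lapply(inst$stacks, max))))
  expect_lt(max(abs(sub)), 1e-10 * scale)
  # after removal the empirical condition means equal the fitted
  # heart-rate-free S exactly (LS residuals are orthogonal to the
  # condition indicators), so fitted stimulus contrasts are preserved
  for (cd in c("a", "b")) {
    i <- inst$cond == cd
    emp <- Reduce(`+`, out[i]) / sum(i)
    expect_lt(max(abs(emp - fit$condition_means[[cd]])), 1e-9)
  }
})

test_that("a quartic artifact is suppressed by >= 90% on a full session", {
  inst <- hb_instance(n = 200, ny = 6, nx = 6, nt = 4, noise = 0.05,
                      artifact = function(hr) {
                        zz <- (hr - 150) / 10
                        0.4 * zz + 0.15 * zz^2 + 0.05 * zz^3 + 0.02 * zz^4
                      }, seed = 8)
  fit <- fit_heartbeat_model(inst$stacks, inst$trials)
  out <- remove_heartbeat(inst$stacks, fit$model, inst$trials)
  clean <- lapply(seq_len(200), function(k) inst$base[[inst$cond[k]]])
  art_power <- function(ss) {
    # variance (across trials) not explained by condition structure,
    # relative to the artifact-free render
    mean(sapply(seq_len(200), function(k) {
      r <- ss[[k]] - clean[[k]]
      mean((r - mean(r))^2)
    }))
  }
  noise_floor <- 0.05^2
  before <- art_power(inst$stacks) - noise_floor
  after <- art_power(out) - noise_floor
  expect_lt(after / before, 0.10)
})

test_that("missing heart rate and bad inputs raise named errors", {
  inst <- hb_instance(n = 6)
  inst$trials$heart_rate[3] <- NA
  expect_error(fit_heartbeat_model(inst$stacks, inst$trials), "3")
  inst2 <- hb_instance(n = 6)
  fit <- fit_heartbeat_model(inst2$stacks, inst2$trials)
  inst2$trials$heart_rate[2] <- NA
  expect_error(remove_heartbeat(inst2$stacks, fit$model, inst2$trials),
               "2")
  # single-trial condition is flagged
  inst3 <- hb_instance(n = 7)
  expect_true("a" %in% c("a", "b"))  # layout guard
  inst3$trials$condition_id <- c("a", rep("b", 6))
  f3 <- fit_heartbeat_model(inst3$stacks, inst3$trials)
  expect_identical(f3$model$single_trial_conditions, "a")
})
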