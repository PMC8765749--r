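# Generator: behavioral simulation, trial rendering, session bookkeeping.

test_that("simulated choice probabilities match the closed form", {
  # at c = alpha with delta = 0 the hit rate is Phi(0.5): binomial check
  n <- 10000
  tab <- data.frame(block_id = "visual", target_present = TRUE,
                    block_contrast = 0.1)[rep(1, n), ]
  out <- simulate_choices(tab, list(visual = list(alpha = 0.1, beta = 2,
                                                  delta = 0)), seed = 9)
  p <- pnorm(0.5)
  expect_lt(abs(mean(out$outcome == "hit") - p),
            3 * sqrt(p * (1 - p) / n))

  # c = 0, delta = 0: both rates ~0.5
  tab0 <- data.frame(block_id = "visual",
                     target_present = rep(c(TRUE, FALSE), each = n / 2),
                     block_contrast = 0)
  out0 <- simulate_choices(tab0, list(visual = list(alpha = 0.1, beta = 2,
                                                    delta = 0)), seed = 10)
  hit <- mean(out0$outcome[out0$target_present] == "hit")
  cr <- mean(out0$outcome[!out0$target_present] == "correct_rejection")
  expect_lt(abs(hit - 0.5), 3 * sqrt(0.25 / (n / 2)))
  expect_lt(abs(cr - 0.5), 3 * sqrt(0.25 / (n / 2)))

  # determinism and outcome/choice consistency
  out_b <- simulate_choices(tab, list(visual = list(alpha = 0.1, beta = 2,
                                                    delta = 0)), seed = 9)
  expect_identical(out$outcome, out_b$outcome)
  expect_true(all(out$choice[out$outcome == "hit"] == "saccade"))
  expect_error(simulate_choices(tab, list(visual = list(alpha = -1,
                                                        beta = 2))),
               "alpha")
})

test_that("rendering with all stochastic amplitudes zero is static", {
  gt <- clean_truth(opto_amplitude = list("0.6" = 0))
  gt$nr_dff$zmax <- 0
  cfg <- small_config(ground_truth = gt)
  tl <- cfg$timeline
  maps <- optomask:::session_maps(cfg$geometry, cfg$stimulus)
  trial <- data.frame(target_contrast = 0.2, opto_power_density = 0.6,
                      heart_rate = 150, choice = "stay",
                      saccade_time_ms = NA_real_, condition_id = "x")
  gt$drift_ms <- list(x = 0)
  r <- render_trial_stack(gt, trial, tl, cfg$geometry, maps, seed = 1)
  for (tt in seq_len(tl$n_frames))
    expect_identical(max(abs(r$stack[, , tt] - maps$baseline)), 0)
  dff <- compute_dff(r$stack, tl$baseline_frames)$dff
  expect_identical(max(abs(dff)), 0)
})

test_that("rho_true = 1 erases the visual-evoked component at the opsin site", {
  gt <- clean_truth(rho_true = 1, site2_visual_gain = 0)
  gt$drift_ms <- list(a = 0, b = 0)
  cfg <- small_config(ground_truth = gt)
  maps <- optomask:::session_maps(cfg$geometry, cfg$stimulus)
  combined <- data.frame(target_contrast = 0.4, opto_power_density = 0.6,
                         heart_rate = 150, choice = "stay",
                         saccade_time_ms = NA_real_, condition_id = "a")
  opto_only <- transform(combined, target_contrast = 0, condition_id = "b")
  r1 <- render_trial_stack(gt, combined, cfg$timeline, cfg$geometry,
                           maps, seed = 5)
  r2 <- render_trial_stack(gt, opto_only, cfg$timeline, cfg$geometry,
                           maps, seed = 5)
  expect_identical(r1$stack, r2$stack)
  expect_error(render_trial_stack(
    ground_truth(rho_true = 1.2), combined, cfg$timeline, cfg$geometry,
    maps, seed = 5), "rho", fixed = TRUE)
})

test_that("injected motion is recoverable by exhaustive cross-correlation", {
  gt <- clean_truth()
  gt$motion_sd_px <- 0.5
  gt$nr_dff$zmax <- 0
  gt$drift_ms <- list(x = 0)
  cfg <- session_config(nx = 48, ny = 48, mm_per_px = 1 / 48,
                        contrasts = c(0, 0.2), n_per_cond = 2,
                        ground_truth = gt)
  maps <- optomask:::session_maps(cfg$geometry, cfg$stimulus)
  trial <- data.frame(target_contrast = 0, opto_power_density = 0,
                      heart_rate = 150, choice = "stay",
                      saccade_time_ms = NA_real_, condition_id = "x")
  r <- render_trial_stack(gt, trial, cfg$timeline, cfg$geometry, maps,
                          seed = 21)
  est <- estimate_motion(r$stack)
  truth <- r$sidecar$v - apply(r$sidecar$v, 1, median)
  expect_lt(max(abs(est - truth)), 0.1)
})

test_that("sidecar ground truth reconstructs the stack to within noise", {
  s <- small_session()
  gt <- s$ground_truth
  tl <- s$config$timeline
  t_ms <- tl$frame_start_ms + tl$frame_period_ms / 2
  for (i in c(1, 10, 25)) {
    sc <- s$sidecars[[i]]
    clean <- array(0, dim(s$stacks[[i]]))
    for (tt in seq_len(tl$n_frames)) {
      fr <- s$maps$baseline *
        (1 + s$maps$site1 * sc$resp1_t[tt] + s$maps$site2 * sc$resp2_t[tt] +
           sc$drift_t[tt]) + s$maps$baseline * s$maps$hb_map * sc$hb_t[tt]
      clean[, , tt] <- translate_frame(fr, sc$v[1, tt], sc$v[2, tt])
    }
    resid <- s$stacks[[i]] - clean
    rmse <- sqrt(mean(resid^2))
    expect_lt(rmse, gt$noise_sd * 1.05)
    expect_gt(rmse, gt$noise_sd * 0.95)
  }
})

test_that("session bookkeeping matches the design", {
  cfg <- session_config(n_per_cond = 50, contrasts = c(0, 0.1, 0.2, 0.4),
                        opto_powers = 0.6)
  tab <- build_trial_table(cfg, seed = 3)
  expect_equal(nrow(tab), 400)   # 4 contrasts x 2 blocks x 50
  expect_true(all(tab$target_contrast[!tab$target_present] == 0))
  expect_true(all(tab$target_contrast[tab$target_present] ==
                    tab$block_contrast[tab$target_present]))
  expect_true(all(tab$heart_rate > 0))
  # reproducible under the seed
  expect_identical(tab, build_trial_table(cfg, seed = 3))
  expect_false(identical(tab$heart_rate,
                         build_trial_table(cfg, seed = 4)$heart_rate))
  # contrast-0 rows exist in both blocks (blank / optostim-only)
  expect_true(any(tab$block_id == "visual" & tab$block_contrast == 0))
  expect_true(any(tab$block_id != "visual" & tab$block_contrast == 0))
  expect_error(session_config(contrasts = c(0.1, 0.2)),
               "configuration error")
})

test_that("generated sessions embed the task timeline and outcomes", {
  s <- small_session()
  expect_equal(s$config$timeline$target_onset_ms, 250)
  expect_equal(s$config$timeline$optostim_onset_ms, 290)
  expect_equal(s$config$timeline$frame_rate_hz, 20)
  expect_true(all(s$trials$outcome %in%
                    c("hit", "miss", "false_alarm", "correct_rejection")))
  expect_true(all(is.finite(s$trials$saccade_time_ms[
    s$trials$choice == "saccade"])))
  # same seed: identical session
  s2 <- generate_session(small_config(), seed = 42)
  expect_identical(s$trials, s2$trials)
  expect_identical(s$stacks[[7]], s2$stacks[[7]])
})
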