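# dF/F, ROI selection, detrending, window summary, z-scoring.

test_that("dF/F is exact on constructed stacks", {
  base <- matrix(50, 8, 8)
  stack <- array(rep(base, 6), c(8, 8, 6))
  d <- compute_dff(stack, 1:3)
  expect_identical(max(abs(d$dff)), 0)

  stack[, , 5] <- 1.02 * base
  d <- compute_dff(stack, 1:3)
  expect_equal(max(abs(d$dff[, , 5] - 0.02)), 0, tolerance = 1e-14)
  expect_lt(max(abs(apply(d$dff[, , 1:3], c(1, 2), mean))), 1e-15)

  stack[1, 1, ] <- 0
  expect_error(compute_dff(stack, 1:3), "1 pixel")
})

test_that("ROI search is exhaustive with lexicographic tie-break", {
  # Gaussian bump: window centered on it
  m <- gaussian_site_map(40, 40, c(26, 14), 8)
  roi <- select_roi(m, roi_mm = 10 / 64, mm_per_px = 1 / 64)
  expect_equal(roi$width_px, 10)
  # brute-force oracle
  best <- c(-Inf, 1, 1)
  for (y0 in 1:31) for (x0 in 1:31) {
    v <- mean(m[y0 + 0:9, x0 + 0:9])
    if (v > best[1]) best <- c(v, y0, x0)
  }
  expect_equal(c(roi$y0, roi$x0), best[2:3])
  expect_lt(abs((roi$y0 + roi$height_px / 2) - 14), 1.6)
  expect_lt(abs((roi$x0 + roi$width_px / 2) - 26), 1.6)

  # flat map: tie-break at (1, 1)
  flat <- select_roi(matrix(1, 20, 20), roi_mm = 5 / 64,
                     mm_per_px = 1 / 64)
  expect_equal(c(flat$x0, flat$y0), c(1, 1))

  # 1 mm at 64 px/mm is a 64 x 64 window
  r64 <- select_roi(matrix(0, 64, 64), roi_mm = 1, mm_per_px = 1 / 64)
  expect_equal(c(r64$width_px, r64$height_px), c(64, 64))
  expect_error(select_roi(matrix(0, 32, 32), 1, 1 / 64), "larger")
})

test_that("random maps: integral-image search equals brute force", {
  set.seed(12)
  for (rep in 1:5) {
    m <- matrix(rnorm(30 * 30), 30, 30)
    roi <- select_roi(m, roi_mm = 7, mm_per_px = 1)
    best <- c(-Inf, 1, 1)
    for (y0 in 1:24) for (x0 in 1:24) {
      v <- mean(m[y0 + 0:6, x0 + 0:6])
      if (v > best[1] + 1e-12) best <- c(v, y0, x0)
    }
    expect_equal(c(roi$y0, roi$x0), best[2:3])
    expect_equal(roi$mean, best[1], tolerance = 1e-12)
  }
})

test_that("detrending removes common and private linear trends", {
  tl <- build_timeline()
  t_s <- tl$frame_start_ms / 1000
  pre <- tl$baseline_frames
  n <- 6
  # common slope on all trials of one condition, zero signal
  R <- matrix(rep(0.3 * t_s + 0.1, n), n, tl$n_frames, byrow = TRUE)
  det <- detrend(R, rep("a", n), pre, tl$frame_start_ms)
  expect_lt(max(abs(det$timecourses)), 1e-12)

  # private slopes +-m recovered exactly (they cancel in the mean)
  m_true <- 0.07
  R2 <- rbind(m_true * t_s, -m_true * t_s,
              matrix(0, 2, tl$n_frames))
  det2 <- detrend(R2, rep("a", 4), pre, tl$frame_start_ms)
  expect_equal(det2$m_k[1:2], c(m_true, -m_true), tolerance = 1e-10)
  expect_lt(max(abs(det2$timecourses)), 1e-10)

  # post-condition: flat zero pre-stimulus conditional means
  set.seed(4)
  R3 <- matrix(rnorm(8 * tl$n_frames, 0, 0.2), 8, tl$n_frames) +
    rep(0.5 * t_s, each = 8)
  det3 <- detrend(R3, rep(c("a", "b"), 4), pre, tl$frame_start_ms)
  for (cd in c("a", "b")) {
    cm <- colMeans(det3$timecourses[det3$conditions == cd, pre])
    expect_lt(abs(mean(cm)), 1e-8)
    expect_lt(abs(coef(lm(cm ~ t_s[pre]))[2]), 1e-6)
  }

  # a trial with < 2 valid frames is flagged with m_k = 0
  vm <- matrix(TRUE, 4, tl$n_frames)
  vm[2, 2:tl$n_frames] <- FALSE
  det4 <- detrend(R2, rep("a", 4), pre, tl$frame_start_ms,
                  valid_mask = vm)
  expect_true(2 %in% det4$flagged)
  expect_identical(det4$m_k[2], 0)
})

test_that("drift injection does not bias extracted responses by > 2%", {
  gt_clean <- clean_truth()
  gt_clean$noise_sd <- 0.05     # keeps sigma_blank > 0; same draw both renders
  gt_drift <- clean_truth()
  gt_drift$noise_sd <- 0.05
  gt_drift$drift_ms_sd <- 0.01
  gt_drift$drift_mk_sd <- 0.01
  # identical seeds: only the drift differs between the paired renders
  s1 <- preprocess_session(
    generate_session(small_config(ground_truth = gt_clean), seed = 77),
    stages = character(0))
  s2 <- preprocess_session(
    generate_session(small_config(ground_truth = gt_drift), seed = 77),
    stages = character(0))
  vis1 <- s1$responses$R[s1$responses$target_contrast == 0.4]
  vis2 <- s2$responses$R[s2$responses$target_contrast == 0.4]
  expect_lt(abs(mean(vis2) - mean(vis1)), 0.02 * abs(mean(vis1)))
})

test_that("window summary picks the right frames", {
  tl <- build_timeline()
  expect_equal(window_frames_of(tl), 9:11)   # 3 frames at 20 Hz
  v <- rep(9, tl$n_frames)
  expect_equal(summarize_response(v, tl), 9)
  v[9:11] <- c(1, 2, 3)
  expect_equal(summarize_response(v, tl), 2)
  expect_error(window_frames_of(tl, c(-100, -50)), "window")
})

test_that("z-scoring uses the blank-trial mean and unbiased SD", {
  set.seed(2)
  blanks <- rnorm(20)
  others <- rnorm(10, 5)
  r <- c(blanks, others)
  is_blank <- rep(c(TRUE, FALSE), c(20, 10))
  zs <- zscore_responses(r, is_blank)
  expect_equal(mean(zs$z[is_blank]), 0, tolerance = 1e-12)
  expect_equal(sd(zs$z[is_blank]), 1, tolerance = 1e-12)
  expect_equal(zscore_responses(c(blanks, mean(blanks) + sd(blanks)),
                                c(is_blank[1:20], FALSE))$z[21], 1,
               tolerance = 1e-12)
  expect_error(zscore_responses(r, rep(c(TRUE, FALSE), c(1, 29))),
               "blank")
  expect_error(zscore_responses(rep(1, 10), rep(TRUE, 10)), "sigma")
})

test_that("the extraction chain is affine in the injected amplitude", {
  gt1 <- clean_truth()
  gt1$noise_sd <- 0.1
  gt2 <- clean_truth()
  gt2$noise_sd <- 0.1
  gt2$nr_dff <- modifyList(gt1$nr_dff, list(zmax = 2 * gt1$nr_dff$zmax))
  gt2$opto_amplitude <- list("0.6" = 2 * gt1$opto_amplitude[["0.6"]])
  s1 <- preprocess_session(
    generate_session(small_config(ground_truth = gt1), seed = 55),
    stages = character(0))
  s2 <- preprocess_session(
    generate_session(small_config(ground_truth = gt2), seed = 55),
    stages = character(0))
  m1 <- mean(s1$responses$R[s1$responses$target_contrast == 0.4])
  m2 <- mean(s2$responses$R[s2$responses$target_contrast == 0.4])
  expect_equal(m2 / m1, 2, tolerance = 0.05)
})
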