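# Performance tabulation, psychometric model, joint fitting, bootstrap.

mk_outcomes <- function(block, contrast, n_present, n_hits, n_absent,
                        n_cr, power = 0) {
  data.frame(
    block_id = block,
    block_contrast = contrast,
    target_present = rep(c(TRUE, FALSE), c(n_present, n_absent)),
    opto_power_density = power,
    outcome = c(rep(c("hit", "miss"), c(n_hits, n_present - n_hits)),
                rep(c("correct_rejection", "false_alarm"),
                    c(n_cr, n_absent - n_cr))))
}

test_that("performance tabulation counts and rescales correctly", {
  tab <- rbind(mk_outcomes("visual", 0.2, 10, 7, 10, 9),
               mk_outcomes("visual", 0.4, 10, 10, 10, 0))
  perf <- tabulate_performance(tab)
  expect_equal(perf$p_hit, c(0.7, 1.0))
  expect_equal(perf$p_cr, c(0.9, 0.0))
  expect_equal(perf$p_hit_hat, c(0.005 + 0.99 * 0.7, 0.995))
  expect_equal(perf$p_cr_hat, c(0.005 + 0.99 * 0.9, 0.005))
  # P = 0.5 is a fixed point
  p5 <- tabulate_performance(mk_outcomes("visual", 0.2, 10, 5, 10, 5))
  expect_equal(p5$p_hit_hat, 0.5)
  # zero absent trials: criterion unidentifiable
  expect_error(tabulate_performance(
    mk_outcomes("visual", 0.2, 10, 7, 0, 0)), "absent")
})

test_that("psychometric probabilities match the error-function oracle", {
  p <- psychometric_probability(0.1, alpha = 0.1, beta = 2, delta = 0)
  expect_equal(p$p_hit, pnorm(0.5))
  expect_equal(p$p_cr, pnorm(0.5))
  p0 <- psychometric_probability(0, 0.1, 2, 0)
  expect_equal(c(p0$p_hit, p0$p_cr), c(0.5, 0.5))
  # d' = (0.2/0.1)^2 = 4: hit = Phi(1.8), cr = Phi(2.2)
  p2 <- psychometric_probability(0.2, 0.1, 2, 0.2)
  expect_equal(p2$p_hit, pnorm(1.8), tolerance = 1e-12)
  expect_equal(p2$p_cr, pnorm(2.2), tolerance = 1e-12)
  expect_equal(p2$p_hit, 0.9640697, tolerance = 1e-6)
  expect_equal(p2$p_cr, 0.9860966, tolerance = 1e-6)
  expect_error(psychometric_probability(0.1, -1, 2), "alpha")

  # monotonicity: in c (both), in delta (hit down, cr up)
  cs <- seq(0.01, 0.5, length.out = 40)
  pr <- psychometric_probability(cs, 0.1, 1.5, 0.3)
  expect_true(all(diff(pr$p_hit) > 0))
  expect_true(all(diff(pr$p_cr) > 0))
  ds <- seq(-1, 1, length.out = 21)
  ph <- sapply(ds, function(d)
    psychometric_probability(0.15, 0.1, 1.5, d)$p_hit)
  pc <- sapply(ds, function(d)
    psychometric_probability(0.15, 0.1, 1.5, d)$p_cr)
  expect_true(all(diff(ph) < 0))
  expect_true(all(diff(pc) > 0))
})

test_that("bias-corrected percent correct", {
  fit <- list(alpha = 0.07, beta = 1.8)
  expect_equal(round(bias_corrected_percent_correct(fit, 0.07)), 69)
  expect_equal(bias_corrected_percent_correct(fit, 0), 50)
  cs <- seq(0, 2, length.out = 50)
  pc <- bias_corrected_percent_correct(list(alpha = 0.1, beta = 1), cs)
  expect_true(all(diff(pc) >= 0))          # saturates at 100 numerically
  expect_true(all(diff(pc[cs[-1] < 0.5]) > 0))
  expect_gt(max(pc), 99)
})

test_that("joint fit recovers parameters and respects symmetry", {
  gt <- list(visual = list(alpha = 0.1, beta = 1.5, delta = 0.1),
             opto0.6 = list(alpha = 0.15, beta = 1.5, delta = 0.3))
  cfg <- session_config(n_per_cond = 1200,
                        contrasts = c(0, 0.05, 0.1, 0.2, 0.4))
  tab <- simulate_choices(build_trial_table(cfg, seed = 21), gt,
                          seed = 22)
  fit <- fit_psychometric_joint(
    tabulate_performance(tab[tab$opto_power_density == 0, ]),
    tabulate_performance(tab[tab$opto_power_density > 0, ]))
  expect_lt(abs(fit$blocks$visual$alpha / 0.1 - 1), 0.10)
  expect_lt(abs(fit$blocks$opto$alpha / 0.15 - 1), 0.10)
  expect_lt(abs(fit$beta / 1.5 - 1), 0.12)
  expect_lt(abs(fit$blocks$visual$delta - 0.1), 0.08)
  expect_lt(abs(fit$blocks$opto$delta - 0.3), 0.08)
  expect_equal(normalized_threshold(fit),
               fit$blocks$opto$alpha / fit$blocks$visual$alpha)

  # symmetric proportions: delta ~ 0
  perf <- tabulate_performance(rbind(
    mk_outcomes("visual", 0.05, 200, 110, 200, 110),
    mk_outcomes("visual", 0.1, 200, 138, 200, 138),
    mk_outcomes("visual", 0.2, 200, 190, 200, 190)))
  f1 <- fit_psychometric_joint(perf)
  expect_lt(abs(f1$blocks$visual$delta), 0.02)

  # likelihood invariant under contrast-row permutation
  f2 <- fit_psychometric_joint(perf[c(3, 1, 2), ])
  expect_equal(f1$nll, f2$nll, tolerance = 1e-6)
  expect_equal(f1$blocks$visual$alpha, f2$blocks$visual$alpha,
               tolerance = 1e-5)
})

test_that("bootstrap_behavior is reproducible and orders uncertainty", {
  gt <- list(visual = list(alpha = 0.1, beta = 1.5, delta = 0.1),
             opto0.6 = list(alpha = 0.15, beta = 1.5, delta = 0.3))
  cfg <- session_config(n_per_cond = 40,
                        contrasts = c(0, 0.05, 0.1, 0.2, 0.4))
  tab <- simulate_choices(build_trial_table(cfg, seed = 31), gt,
                          seed = 32)
  b1 <- bootstrap_behavior(tab, n_boot = 40, seed = 8)
  b2 <- bootstrap_behavior(tab, n_boot = 40, seed = 8)
  expect_identical(b1[["0.6"]]$draws, b2[["0.6"]]$draws)
  s <- b1[["0.6"]]
  expect_true(all(is.finite(c(s$rho_behavior, s$rho_behavior_sd,
                              s$p_threshold, s$p_criterion))))
  expect_gt(s$rho_behavior, 1)   # threshold rises under optostim

  # larger sessions shrink the bootstrap SD
  cfg_big <- session_config(n_per_cond = 400,
                            contrasts = c(0, 0.05, 0.1, 0.2, 0.4))
  tab_big <- simulate_choices(build_trial_table(cfg_big, seed = 33), gt,
                              seed = 34)
  b3 <- bootstrap_behavior(tab_big, n_boot = 40, seed = 8)
  expect_lt(b3[["0.6"]]$alpha_sd[["visual"]],
            s$alpha_sd[["visual"]])
  expect_error(bootstrap_behavior(tab, n_boot = 1), "n_boot")
})
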