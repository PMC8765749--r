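# Shared fixtures. Sessions are generated in code (no stored data); the
# moderately sized ones are memoized so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small imaging config: 24x24 px, full default timeline
small_config <- function(...) {
  session_config(nx = 24, ny = 24, mm_per_px = 1 / 24,
                 stimulus = stimulus_spec(
                   weber_contrast = 0.2,
                   site_centers_px = list(c(8, 8), c(17, 17)),
                   site_fwhm_px = 6),
                 contrasts = c(0, 0.1, 0.2, 0.4),
                 n_per_cond = 8, ...)
}

small_session <- function() memo("small_session", {
  generate_session(small_config(), seed = 42)
})

# a noiseless, artifact-free truth for exactness tests
clean_truth <- function(...) {
  ground_truth(hb_amplitude = 0, motion_sd_px = 0, drift_ms_sd = 0,
               drift_mk_sd = 0, noise_sd = 0, ...)
}

# textured static frame for registration tests (two spatial scales, like
# the generator's baseline: broad unevenness plus fine vasculature)
textured_frame <- function(ny = 32, nx = 32, seed = 7) {
  withr_seed <- get("withr_seed", asNamespace("optomask"))
  smap <- get("smooth_random_map", asNamespace("optomask"))
  withr_seed(seed, {
    m <- smap(ny, nx, 3) + smap(ny, nx, 1.2)
  })
  100 + 7 * m
}

# exhaustive integer-shift search maximizing the Pearson correlation of
# the overlapping region (normalized, so overlap size does not bias it)
oracle_shift <- function(frame, ref, max_shift = 4) {
  best <- c(0, 0); bestv <- -Inf
  ny <- nrow(ref); nx <- ncol(ref)
  for (sy in -max_shift:max_shift) for (sx in -max_shift:max_shift) {
    ys <- max(1, 1 + sy):min(ny, ny + sy)
    xs <- max(1, 1 + sx):min(nx, nx + sx)
    v <- cor(as.vector(frame[ys, xs]),
             as.vector(ref[ys - sy, xs - sx]))
    if (v > bestv) { bestv <- v; best <- c(sx, sy) }
  }
  best
}
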