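test_that("normalizations behave as affine/scale maps and reject degenerate input", {
  expect_equal(normalize_minmax(c(2, 4, 6)), c(0, 0.5, 1))
  v <- c(0.3, 2.2, 1.1, 0.9)
  expect_equal(normalize_minmax(normalize_minmax(v)), normalize_minmax(v)) # idempotent
  expect_equal(which.max(normalize_minmax(v)), which.max(v))
  expect_error(normalize_minmax(rep(3, 4)), "constant")

  expect_equal(normalize_by_mean(c(1, 2, 3)), c(0.5, 1, 1.5))
  expect_equal(normalize_by_mean(5 * v), normalize_by_mean(v))  # scale invariant
  expect_equal(normalize_by_mean(rep(2, 5)), rep(1, 5))
  expect_error(normalize_by_mean(c(-1, -2)), "positive")
})

test_that("half-max crossing equals the brute-force segment root to 1e-9", {
  expect_equal(half_max_crossing(4, 0.8, 6, 0.2), 5)
  eps <- 1e-6
  expect_equal(half_max_crossing(0, 0.5 + eps, 1, 0.5 - eps), 0.5)
  expect_equal(half_max_crossing(2, 0.5, 3, 0.1), 2)   # endpoint at 0.5 -> that sample
  # brute-force root of the linear segment on a dense grid, 30 random cases
  withr::with_seed(42, {
    for (i in 1:30) {
      t1 <- runif(1, 0, 20); t2 <- t1 + runif(1, 0.1, 6)
      f1 <- runif(1, 0.51, 1); f2 <- runif(1, 0, 0.49)
      seg <- function(t) f1 + (t - t1) / (t2 - t1) * (f2 - f1) - 0.5
      root <- uniroot(seg, c(t1, t2), tol = 1e-12)$root
      expect_equal(half_max_crossing(t1, f1, t2, f2), root, tolerance = 1e-9)
    }
  })
  expect_error(half_max_crossing(0, 0.8, 1, 0.7), "bracket")
  expect_error(half_max_crossing(0, 0.6, 1, 0.6), "degenerate")
})

test_that("crest_time returns the earliest maximum sample", {
  expect_equal(crest_time(c(0, 6, 12), c(0, 1, 0.3)), 6)
  expect_equal(crest_time(c(0, 6, 7, 12), c(0, 1, 1, 0.3)), 6)  # tie -> earliest
  p <- waveform_params(13, 9, 15)
  tt <- seq(0, 23.75, by = 0.25)
  expect_equal(crest_time(tt, eval_waveform(p, tt)), 13, tolerance = 0.125)
})

test_that("fwhm handles symmetric, circular and multi-peak curves", {
  tt <- seq(0, 23.9, by = 0.1)
  res <- fwhm(tt, normalize_minmax(cos(2 * pi * tt / 24)))
  expect_equal(res$fwhm, 12, tolerance = 0.05)

  # crest near midnight: super-half-max region wraps across the boundary
  p <- waveform_params(peak_phase = 23, rise = 8, fall = 16, sharpness = 1.5)
  res2 <- fwhm(tt, eval_waveform(p, tt))
  oracle <- analytic_fwhm(p)
  expect_identical(res2$n_segments, 1L)
  expect_equal(res2$fwhm, oracle, tolerance = 0.05)
  expect_equal(res2$ascend_cross, (23 - 8 + (8 / pi) * acos(1 - 2 * 0.5^(1 / 1.5))) %% 24,
               tolerance = 0.05)
  expect_gt(res2$ascend_cross, 12)   # ascends late evening
  expect_lt(res2$descend_cross, 12)  # descends after midnight

  # bimodal: two disjoint super-half-max regions, no duration
  bim <- eval_waveform(waveform_params(4, 3, 21, sharpness = 6), tt) +
    eval_waveform(waveform_params(16, 3, 21, sharpness = 6), tt)
  res3 <- fwhm(tt, bim)
  expect_identical(res3$n_segments, 2L)
  expect_true(is.na(res3$fwhm))

  expect_error(fwhm(tt, rep(1, length(tt))), "constant")
})

test_that("fwhm estimate converges to ground truth as sampling gets denser", {
  p <- waveform_params(peak_phase = 9, rise = 10, fall = 14, sharpness = 2.5)
  truth <- true_fwhm(p)
  err <- vapply(c(2, 0.5, 0.05), function(step) {
    tt <- seq(0, 24 - step, by = step)
    abs(fwhm(tt, eval_waveform(p, tt))$fwhm - truth)
  }, numeric(1))
  expect_true(all(diff(err) < 0))   # strictly decreasing error
  expect_lt(err[3], 1e-3)
})

test_that("circular shift moves crest and crossings but leaves fwhm unchanged", {
  tt <- seq(0, 23.5, by = 0.5)
  p0 <- waveform_params(peak_phase = 6, rise = 9, fall = 15, sharpness = 2)
  base <- fwhm(tt, eval_waveform(p0, tt))
  for (delta in c(4, 11.5, 19)) {
    ps <- waveform_params(peak_phase = (6 + delta) %% 24, rise = 9, fall = 15,
                          sharpness = 2)
    shifted <- fwhm(tt, eval_waveform(ps, tt))
    expect_equal(shifted$fwhm, base$fwhm, tolerance = 1e-6)
    expect_equal(shifted$ascend_cross %% 24, (base$ascend_cross + delta) %% 24,
                 tolerance = 1e-6)
    expect_equal(shifted$descend_cross %% 24, (base$descend_cross + delta) %% 24,
                 tolerance = 1e-6)
  }
})

test_that("sections split the cycle exactly and mirror generator skew", {
  tt <- seq(0, 23.9, by = 0.1)
  p <- waveform_params(peak_phase = 13, rise = 9, fall = 15)
  s <- sections(tt, eval_waveform(p, tt))
  expect_equal(s$ascending, 9, tolerance = 0.1)
  expect_equal(s$descending, 15, tolerance = 0.1)
  expect_identical(s$ascending + s$descending, 24)     # exact closure
  sym <- sections(tt, cos(2 * pi * (tt - 12) / 24))
  expect_equal(sym$ascending, 12, tolerance = 0.1)
  # a descending section growing 16 h -> 18 h is a +12.5% change
  expect_equal(percent_change(16, 18), 12.5)
})

test_that("detrending removes a linear ramp and preserves the oscillation", {
  tt <- seq(0, 96, by = 1 / 3)
  ramp <- data.frame(time_h = tt, value = 0.5 * tt)
  det <- detrend_trace(ramp, window = 24)
  interior <- tt > 12 & tt < 84
  expect_lt(max(abs(det$value[interior])), 0.01 * diff(range(ramp$value)))

  osc <- sin(2 * pi * tt / 24)
  det2 <- detrend_trace(data.frame(time_h = tt, value = osc), window = 24)
  expect_gt(cor(det2$value[interior], osc[interior]), 0.99)
  expect_error(detrend_trace(data.frame(time_h = 0:5, value = 0:5), window = 24),
               "longer")
})

test_that("period scan recovers free-running periods and flags pure noise", {
  p239 <- waveform_params(peak_phase = 12, rise = 11.95, fall = 11.95, period = 23.9)
  tr <- simulate_trace(p239, duration = 96, interval = 1 / 3)
  est <- period_estimate(tr)
  expect_true(est$rhythmic)
  expect_equal(est$period, 23.9, tolerance = 0.0501)

  p24 <- waveform_params(peak_phase = 12, rise = 12, fall = 12, period = 24)
  expect_equal(period_estimate(simulate_trace(p24, 96, 1 / 3))$period, 24,
               tolerance = 0.0501)

  # detrending must not bias the scan: slope 0.1/h on top of the rhythm
  tr_slope <- tr
  tr_slope$value <- tr_slope$value + 0.1 * tr_slope$time_h
  est_d <- period_estimate(detrend_trace(tr_slope, window = 24))
  expect_equal(est_d$period, 23.9, tolerance = 0.0501)

  # pure noise is flagged non-rhythmic, not assigned a period
  flagged <- vapply(1:20, function(s) {
    noise <- withr::with_seed(s, data.frame(time_h = tt <- seq(0, 96, 1 / 3),
                                            value = rnorm(length(tt))))
    period_estimate(noise)$rhythmic
  }, logical(1))
  expect_lt(mean(flagged), 0.2)
  expect_error(period_estimate(data.frame(time_h = 0:30, value = rnorm(31))), "span")
})

test_that("multi-day traces split into per-cycle curves for section analysis", {
  p <- waveform_params(peak_phase = 13, rise = 9, fall = 15)
  tr <- simulate_trace(p, duration = 72, interval = 0.25)
  cycles <- split_cycles(tr, period = 24)
  expect_gte(length(cycles), 2)
  for (cy in cycles[1:2]) {
    s <- sections(cy$time_h, cy$value)
    expect_equal(s$ascending, 9, tolerance = 0.3)
  }
})
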