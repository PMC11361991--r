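test_that("flow segmentation finds cycle starts of a sinusoid", {
  fs <- 100; T <- 4
  t <- seq(0, 20, by = 1 / fs)
  seg <- segment_breaths(sin(2 * pi * t / T), "flow", fs = fs)
  spacing <- diff(seg$boundaries)
  expect_true(all(abs(spacing - T * fs) <= 1))
  expect_error(segment_breaths(rep(0, 500), "flow", fs = fs), "no complete cycle")
})

test_that("flow segmentation is invariant to noise below the hysteresis band", {
  fs <- 100; T <- 4
  t <- seq(0, 20, by = 1 / fs)
  clean <- sin(2 * pi * t / T)
  seg0 <- segment_breaths(clean, "flow", fs = fs)
  set.seed(5)
  # band is 2% of peak; keep perturbation safely below half of it
  noisy <- clean + runif(length(t), -0.004, 0.004)
  seg1 <- segment_breaths(noisy, "flow", fs = fs)
  expect_equal(seg1$n_cycles, seg0$n_cycles)
  expect_true(all(abs(seg1$boundaries - seg0$boundaries) <= 2))
})

test_that("displacement segmentation picks separated minima", {
  fs <- 50; T <- 4
  t <- seq(0, 20, by = 1 / fs)
  seg <- segment_breaths(1 - cos(2 * pi * t / T), "displacement",
                         fs = fs, period = T)
  expect_true(all(abs(diff(seg$boundaries) - T * fs) <= 1))
  expect_error(segment_breaths(rep(1, 300), "displacement", fs = fs),
               "period")
})

test_that("tidal volume integrates the inspiratory flow", {
  fs <- 100
  seg <- structure(list(boundaries = c(1L, 401L, 801L), n_cycles = 2L),
                   class = "breath_segmentation")
  expect_equal(tidal_volumes(rep(0, 900), seg, dt = 1 / fs)$vt, c(0, 0))
  # half-sine inspiratory flow, amplitude A over tau seconds: VT = 2 A tau / pi
  t <- seq(0, 8, by = 1 / fs)
  A <- 0.8; tau <- 2
  flow <- ifelse(t %% 4 < tau, A * sin(pi * (t %% 4) / tau), -0.2)
  vt <- tidal_volumes(flow, seg, dt = 1 / fs)
  expect_equal(vt$vt, rep(2 * A * tau / pi, 2), tolerance = 1e-3)
  expect_true(all(vt$vt_exp > 0))
  expect_error(tidal_volumes(flow, seg, dt = 0), "dt")
})

test_that("excursion is peak-to-trough and shift-invariant", {
  seg <- structure(list(boundaries = c(1L, 101L, 201L), n_cycles = 2L),
                   class = "breath_segmentation")
  x <- sin(seq(0, 4 * pi, length.out = 201))
  e <- excursions(x, seg)
  expect_equal(e$excursion, rep(2, 2), tolerance = 1e-3)
  expect_equal(excursions(x + 10, seg)$excursion, e$excursion)
})

test_that("cycle normalization resamples to n_points and averages", {
  fs <- 100; T <- 2
  t <- seq(0, 8, by = 1 / fs)
  x <- sin(2 * pi * t / T)
  seg <- structure(list(boundaries = seq(1L, 801L, by = 200L), n_cycles = 4L),
                   class = "breath_segmentation")
  avg <- normalize_cycles(x, seg)
  expect_equal(nrow(avg), 20L)
  # identical cycles: average equals one resampled cycle
  expect_equal(avg$value, sin(2 * pi * avg$phase), tolerance = 1e-3)
  # antiphase cancellation: cycle 2 is exactly the negative of cycle 1
  i <- 0:400
  y <- ifelse(i <= 200, sin(2 * pi * i / 200), -sin(2 * pi * (i - 200) / 200))
  seg2 <- structure(list(boundaries = c(1L, 201L, 401L), n_cycles = 2L),
                    class = "breath_segmentation")
  avg2 <- normalize_cycles(y, seg2, n_cycles = 2)
  expect_lt(max(abs(avg2$value)), 1e-12)
  expect_error(normalize_cycles(x, seg2, n_cycles = 3), "cycles")
})

test_that("amplitude error and NRMSE behave as relative measures", {
  expect_equal(amplitude_error(1.14, 1.14), 0)
  expect_equal(amplitude_error(1.07, 1), 7)
  expect_equal(amplitude_error(0.93, 1), amplitude_error(1.07, 1))
  expect_error(amplitude_error(1, 0), "obs")
  obs <- sin(seq(0, 2 * pi, length.out = 101))  # grid hits both extrema
  expect_equal(nrmse(obs, obs), 0)
  expect_equal(nrmse(obs + 0.1, obs), 100 * 0.1 / 2, tolerance = 1e-9)
  expect_equal(nrmse(3 * (obs + 0.1), 3 * obs), nrmse(obs + 0.1, obs))
  expect_error(nrmse(obs, rep(1, 101)), "range")
})

test_that("excursion-volume correlation recovers a linear relationship", {
  ex <- c(1, 2, 3, 4)
  expect_equal(disp_vol_correlation(ex, 0.7 * ex)$r, 1)
  set.seed(9)
  e <- runif(100, 0.5, 3)
  v <- 0.6 * e + rnorm(100, 0, 0.15)
  res <- disp_vol_correlation(e, v)
  expect_gt(res$r, 0.9)
  expect_lt(res$p, 1e-6)
  expect_equal(disp_vol_correlation(v, e)$r, res$r)
  expect_error(disp_vol_correlation(c(1, 1, 1), 1:3), "variance")
})

test_that("paired ratio test reports ratios and an exact Wilcoxon p", {
  s <- c(1.0, 1.2, 0.9, 1.4, 1.1, 0.8, 1.3, 1.05)  # distinct, so exact test applies
  r <- paired_ratio_test(s, 2 * s)
  expect_equal(r$ratio_means, 2)
  expect_equal(r$mean_ratio, 2)
  expect_equal(r$p_value, 2 / 2^8)  # all eight signs positive, two-sided
  expect_equal(paired_ratio_test(s, s)$p_value, 1)
  expect_error(paired_ratio_test(s, s[-1]), "equal-length")
  expect_error(paired_ratio_test(c(1, -1), c(1, 2)), "zero spontaneous")
})

test_that("metrics agree across sampling rates for band-limited signals", {
  prof <- p6_profile()
  m50 <- measure_session(generate_session(prof, "spontaneous", seed = 0, fs = 50))
  m200 <- measure_session(generate_session(prof, "spontaneous", seed = 0, fs = 200))
  expect_equal(m50$mean_excursion, m200$mean_excursion, tolerance = 0.01)
  expect_equal(m50$mean_vt, m200$mean_vt, tolerance = 0.01)
})
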