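test_that("cohort sampling is deterministic and degenerates at cv = 0", {
  ref <- mech_params()
  c0 <- sample_cohort(4, seed = 7, cv = 0)
  for (pr in c0) {
    expect_equal(unclass(pr$params)[1:7], unclass(ref)[1:7])
    expect_true(pr$pattern$t_total >= 3 && pr$pattern$t_total <= 6)
  }
  expect_identical(sample_cohort(8, seed = 42), sample_cohort(8, seed = 42))
  expect_false(identical(sample_cohort(8, seed = 42), sample_cohort(8, seed = 43)))
  expect_error(sample_cohort(8, seed = 1, cv = -0.1), "cv")
})

test_that("lognormal variability reproduces the requested cv", {
  c_ab <- unlist(purrr::map(1:500, function(i) {
    purrr::map_dbl(sample_cohort(8, seed = i, cv = 0.2), ~ .x$params$c_ab)
  }))
  cv_hat <- sd(c_ab) / mean(c_ab)
  expect_equal(cv_hat, 0.2, tolerance = 0.15)
  expect_equal(mean(c_ab), 0.4, tolerance = 0.02)  # unit-mean factors
})

test_that("sessions are pure functions of inputs and seed", {
  prof <- participant_profile()
  s1 <- generate_session(prof, "spontaneous", seed = 3)
  s2 <- generate_session(prof, "spontaneous", seed = 3)
  expect_identical(s1$displacement, s2$displacement)
  expect_identical(s1$flow, s2$flow)
  s3 <- generate_session(prof, "spontaneous", seed = 4)
  expect_false(identical(s1$displacement, s3$displacement))
  expect_error(generate_session(prof, "assisted"), "program")
  expect_error(generate_session(prof, "spontaneous", n_breaths = 2), "n_breaths")
})

test_that("zero-noise sessions reproduce the model truth exactly", {
  prof <- participant_profile(noise_disp = 0, noise_flow = 0)
  s <- generate_session(prof, "spontaneous", seed = 1)
  truth <- attr(s, "truth")
  expect_identical(s$displacement, truth$x_di)
  # telescoping: flow integral over a breath = lung volume travel
  fs <- attr(s, "fs")
  seg <- segment_breaths(s$flow, "flow", fs = fs)
  vt <- tidal_volumes(s$flow, seg, dt = 1 / fs)
  for (i in seq_len(seg$n_cycles)) {
    idx <- seg$boundaries[i]:(seg$boundaries[i + 1L])
    expect_equal(vt$vt[i], ptp_of(truth$v_l[idx]), tolerance = 0.01)
  }
})

test_that("robotic assistance strictly increases excursion", {
  prof <- p6_profile()
  sp <- generate_session(prof, "spontaneous", seed = 2)
  as_ <- generate_session(prof, "assisted", program = robot_program(), seed = 2)
  expect_gt(measure_session(as_)$mean_excursion,
            measure_session(sp)$mean_excursion)
  # truth invariants hold on generated sessions
  truth <- attr(as_, "truth")
  p <- prof$params
  expect_equal(truth$p_pl, (truth$v_ab + truth$v_rc) / p$c_pl)
  expect_equal(truth$x_di, 100 * truth$v_ab * 1e-3 / p$a_di)
})

test_that("amplitude calibration is linear in the excursion target", {
  prof <- p6_profile()  # calibrated to excursion 1.14 cm, VT 0.83 L
  m <- measure_session(generate_session(prof, "spontaneous", seed = 0))
  expect_equal(m$mean_excursion, 1.14, tolerance = 0.01)
  expect_equal(m$mean_vt, 0.83, tolerance = 0.01)
  # doubling the excursion target doubles a_dim (the volume target moves too,
  # since a doubled diaphragm swing already displaces more lung volume)
  prof2 <- calibrate_amplitudes(participant_profile(noise_disp = 0, noise_flow = 0),
                                target_excursion = 2 * 1.14, target_vt = 1.8)
  expect_equal(prof2$pattern$a_dim, 2 * prof$pattern$a_dim, tolerance = 0.01)
})

test_that("calibration recovers a known amplitude pair", {
  pat <- breath_pattern(a_rc = 4, a_dim = 2)
  prof <- participant_profile(pattern = pat, noise_disp = 0, noise_flow = 0)
  m <- measure_session(generate_session(prof, "spontaneous", seed = 0))
  back <- calibrate_amplitudes(prof, target_vt = m$mean_vt,
                               target_excursion = m$mean_excursion)
  expect_equal(back$pattern$a_dim, 2, tolerance = 0.01)
  expect_equal(back$pattern$a_rc, 4, tolerance = 0.01)
  expect_error(calibrate_amplitudes(prof, target_vt = 50, target_excursion = 1),
               "unattainable")
})

test_that("assistance calibration hits both ratio knobs", {
  prof <- p6_profile()
  assist <- p6_assist()
  sp <- measure_session(generate_session(prof, "spontaneous", seed = 0))
  as_ <- measure_session(generate_session(prof, "assisted",
                                          program = assist$program,
                                          pattern = assist$pattern, seed = 0))
  expect_equal(as_$mean_excursion / sp$mean_excursion, 1.95, tolerance = 0.01)
  expect_equal(as_$mean_vt / sp$mean_vt, 2.14, tolerance = 0.01)
})
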