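test_that("noiseless self-generated data is recovered almost exactly", {
  pat <- breath_pattern(a_rc = 5, a_dim = 2.2)
  prof <- participant_profile(pattern = pat, noise_disp = 0, noise_flow = 0)
  rec <- generate_session(prof, "spontaneous", n_breaths = 4, seed = 0, fs = 50)
  ft <- fit_mechanics(rec, spec = fit_spec(c("a_dim", "a_rc")), seed = 1)
  expect_true(ft$converged)
  expect_equal(unname(ft$estimates["a_dim"]), 2.2, tolerance = 0.005)
  expect_equal(unname(ft$estimates["a_rc"]), 5, tolerance = 0.005)
  expect_lt(ft$amplitude_error_disp, 0.5)
  expect_lt(ft$amplitude_error_vol, 0.5)
  expect_lt(ft$nrmse_disp, 0.5)
  expect_lt(ft$nrmse_vol, 0.5)
})

test_that("the objective is stationary at the truth", {
  pat <- breath_pattern(a_rc = 5, a_dim = 2.2)
  prof <- participant_profile(pattern = pat, noise_disp = 0, noise_flow = 0)
  rec <- generate_session(prof, "spontaneous", n_breaths = 3, seed = 0, fs = 50)
  ft <- fit_mechanics(rec, spec = fit_spec("a_dim"), seed = 1)
  # residual sum of squares at the optimum is numerically zero
  expect_lt(ft$ssr, 1e-10)
})

test_that("a compliance can be fitted alongside an amplitude", {
  prof <- participant_profile(params = mech_params(c_ab = 0.55),
                              pattern = breath_pattern(a_rc = 5, a_dim = 2.2),
                              noise_disp = 0, noise_flow = 0)
  rec <- generate_session(prof, "spontaneous", n_breaths = 4, seed = 0, fs = 50)
  # fixed parameters hold the (wrong) reference c_ab; the fit must find 0.55
  ft <- fit_mechanics(rec, params_fixed = mech_params(),
                      spec = fit_spec(c("a_dim", "c_ab")), seed = 1)
  expect_equal(unname(ft$estimates["c_ab"]), 0.55, tolerance = 0.01)
  expect_equal(unname(ft$estimates["a_dim"]), 2.2, tolerance = 0.01)
})

test_that("tidy and glance expose the broom-style views", {
  pat <- breath_pattern(a_rc = 5, a_dim = 2.2)
  prof <- participant_profile(pattern = pat, noise_disp = 0, noise_flow = 0)
  rec <- generate_session(prof, "spontaneous", n_breaths = 3, seed = 0, fs = 50)
  ft <- fit_mechanics(rec, spec = fit_spec(c("a_dim", "a_rc")), seed = 1)
  td <- tidy(ft)
  expect_equal(td$term, c("a_dim", "a_rc"))
  expect_true(all(td$estimate >= td$lower & td$estimate <= td$upper))
  gl <- glance(ft)
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("converged", "ssr", "nrmse_disp", "amplitude_error_vol")
                  %in% names(gl)))
})

test_that("fit_spec validates free parameters and bounds", {
  expect_error(fit_spec(character(0)), "non-empty")
  expect_error(fit_spec("r_rc"), "subset")
  expect_error(fit_spec("a_dim", bounds = list(a_dim = c(5, 1))), "low < high")
  sp <- fit_spec("a_dim", bounds = list(a_dim = c(0, 10)))
  expect_equal(sp$bounds$a_dim, c(0, 10))
})

test_that("recovery experiments are reproducible and unbiased at zero noise", {
  r1 <- recovery_experiment(noise_rel = 0, n_reps = 2, n_breaths = 4,
                            fs = 50, seed = 5)
  r2 <- recovery_experiment(noise_rel = 0, n_reps = 2, n_breaths = 4,
                            fs = 50, seed = 5)
  expect_identical(r1$summary, r2$summary)
  expect_true(all(abs(r1$draws$rel_error) < 0.005))
  expect_true(all(c("bias", "rmse", "median_abs_rel") %in% names(r1$summary)))
})

test_that("more breaths do not degrade noisy recovery", {
  r_short <- recovery_experiment(noise_rel = 0.05, n_reps = 4, n_breaths = 3,
                                 fs = 50, free = "a_dim", seed = 11)
  r_long <- recovery_experiment(noise_rel = 0.05, n_reps = 4, n_breaths = 8,
                                fs = 50, free = "a_dim", seed = 11)
  expect_lte(r_long$summary$median_abs_rel,
             r_short$summary$median_abs_rel + 0.02)
})
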