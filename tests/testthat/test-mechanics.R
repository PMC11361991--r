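test_that("compartment derivatives match the stated first-order forms", {
  p <- mech_params()
  expect_equal(unname(compartment_derivatives(0, 0, 0, 0, 0, 0, p)),
               c(0, 0, 0))
  # unit rib-cage drive from rest: dV_rc = (1 - 0)/R_rc = 1 L/s
  d <- compartment_derivatives(0, 0, 0, 1, 0, 0, p)
  expect_equal(unname(d), c(1, 0, 0))
  # abdominal equilibrium: v_ab/C_ab = p_dimus + p_rex
  d2 <- compartment_derivatives(0, 0.4 * 5, 0, 0, 2, 3, p)
  expect_equal(unname(d2[["dv_ab"]]), 0)
  # generic point agrees with the formulas
  d3 <- compartment_derivatives(0.1, -0.2, 0.05, 1, 2, -1, p)
  expect_equal(unname(d3["dv_rc"]), (1 - 0.1 / p$c_rc) / p$r_rc)
  expect_equal(unname(d3["dv_ab"]), (2 - 1 - (-0.2) / p$c_ab) / p$r_ab)
  expect_equal(unname(d3["dv_l"]), ((-0.2 + 0.1) / p$c_pl - 0.05 / p$c_l) / p$r_l)
})

test_that("non-finite inputs are rejected with the offending field named", {
  p <- mech_params()
  expect_error(compartment_derivatives(NA, 0, 0, 0, 0, 0, p), "v_rc")
  expect_error(compartment_derivatives(0, 0, 0, 0, Inf, 0, p), "p_dimus")
  expect_error(mech_params(c_ab = -1), "c_ab")
  expect_error(pleural_pressure(0, 0, 0), "c_pl")
  expect_error(diaphragm_displacement(1, -0.08), "a_di")
})

test_that("derived pressure and displacement helpers match their formulas", {
  expect_equal(pleural_pressure(0, 0, 0.25), 0)
  expect_equal(pleural_pressure(0.5, 0.5, 0.25), 4)
  expect_equal(pleural_pressure(0.2, 0.7, 0.25), pleural_pressure(0.7, 0.2, 0.25))
  expect_equal(abdominal_pressure(0, 0), 0)
  expect_equal(abdominal_pressure(5, 3), 8)
  x <- c(-2, 0, 1.7)
  expect_equal(abdominal_pressure(x, 0), x)
  expect_equal(diaphragm_displacement(0, 0.08), 0)
  expect_equal(diaphragm_displacement(1.2, 0.08), 1.5)
  v <- c(0.3, 0.9)
  expect_equal(diaphragm_displacement(2 * v, 0.05),
               2 * diaphragm_displacement(v, 0.05))
})

test_that("closed-form step response behaves as the analytic solution", {
  expect_equal(step_response_closed_form(1, 0.4, 3, 0), 0)
  expect_equal(step_response_closed_form(1, 0.4, 3, 1e6), 1.2)
  expect_equal(step_response_closed_form(1, 0.4, 3, 0.4), 1.2 * (1 - exp(-1)))
  expect_error(step_response_closed_form(-1, 0.4, 3, 1), "r")
  expect_error(step_response_closed_form(1, 0.4, 3, -1), "t")
})

test_that("integrator matches the closed-form oracle on constant drives", {
  p <- mech_params()
  t <- seq(0, 10, by = 0.01)
  tr_rc <- simulate_mechanics(p, drive_signals(t, p_rcmus = 2), dt = 1e-3)
  expect_lt(max(abs(tr_rc$v_rc -
                      step_response_closed_form(p$r_rc, p$c_rc, 2, t))), 1e-6)
  tr_ab <- simulate_mechanics(p, drive_signals(t, p_dimus = 1.5), dt = 1e-3)
  expect_lt(max(abs(tr_ab$v_ab -
                      step_response_closed_form(p$r_ab, p$c_ab, 1.5, t))), 1e-6)
})

test_that("steady-state gains are reached after ten time constants", {
  p <- mech_params()
  t <- seq(0, 10, by = 0.01)  # >= 10 * R_ab C_ab = 4 s
  tr <- simulate_mechanics(p, drive_signals(t, p_rex = 3))
  expect_equal(tail(tr$v_ab, 1), p$c_ab * 3, tolerance = 1e-3)
  expect_equal(tail(tr$x_di, 1), 1.5, tolerance = 1e-3)
  expect_equal(tail(tr$v_l, 1), p$c_l * (p$c_ab * 3) / p$c_pl,
               tolerance = 1e-3)
  tr2 <- simulate_mechanics(p, drive_signals(t, p_rcmus = 2, p_dimus = 1))
  expect_equal(tail(tr2$v_rc, 1), p$c_rc * 2, tolerance = 1e-3)
  expect_equal(tail(tr2$v_ab, 1), p$c_ab * 1, tolerance = 1e-3)
})

test_that("trajectory satisfies its pointwise invariants", {
  p <- mech_params()
  pat <- breath_pattern(t_total = 4)
  d <- build_drives(pat, robot_program(t_inflate = 2), n_breaths = 3, fs = 100)
  tr <- simulate_mechanics(p, d)
  expect_equal(tr$p_pl, (tr$v_ab + tr$v_rc) / p$c_pl)
  expect_equal(tr$x_di, 100 * (tr$v_ab * 1e-3) / p$a_di)
  expect_equal(tr$p_ab, d$p_dimus + d$p_rex)
  # displacement trace is an exact scalar multiple of the abdominal volume
  expect_equal(tr$x_di, tr$v_ab * (100 * 1e-3 / p$a_di))
})

test_that("the system is linear: superposition holds to 1e-9 relative", {
  p <- mech_params()
  t <- seq(0, 5, by = 0.01)
  set.seed(11)
  for (i in 1:5) {
    a <- list(p_rcmus = random_smooth(5, 100, amp = 3),
              p_dimus = random_smooth(5, 100, amp = 2),
              p_rex = random_smooth(5, 100, amp = 3))
    b <- list(p_rcmus = random_smooth(5, 100, amp = 2),
              p_dimus = random_smooth(5, 100, amp = 4),
              p_rex = random_smooth(5, 100, amp = 1))
    ta <- simulate_mechanics(p, do.call(drive_signals, c(list(t), a)))
    tb <- simulate_mechanics(p, do.call(drive_signals, c(list(t), b)))
    tab <- simulate_mechanics(p, do.call(
      drive_signals, c(list(t), purrr::map2(a, b, `+`))))
    for (col in c("v_rc", "v_ab", "v_l")) {
      scale <- max(abs(ta[[col]]) + abs(tb[[col]]), 1e-6)
      expect_lt(max(abs(tab[[col]] - ta[[col]] - tb[[col]])) / max(scale),
                1e-9)
    }
  }
})

test_that("halving the integrator step changes samples below 1e-8 L", {
  p <- mech_params()
  pat <- breath_pattern(t_total = 4)
  d <- build_drives(pat, n_breaths = 2, fs = 100)
  tr1 <- simulate_mechanics(p, d, dt = 1e-3)
  tr2 <- simulate_mechanics(p, d, dt = 5e-4)
  for (col in c("v_rc", "v_ab", "v_l")) {
    expect_lt(max(abs(tr1[[col]] - tr2[[col]])), 1e-8)
  }
})

test_that("simulate validates its inputs", {
  p <- mech_params()
  d <- drive_signals(seq(0, 1, by = 0.01), p_rcmus = 1)
  expect_error(simulate_mechanics(p, d, dt = 0), "dt")
  expect_error(simulate_mechanics(p, d, dt = 0.05), "grid step")
  expect_error(simulate_mechanics(p, d, init = c(0, NA, 0)), "init")
  expect_error(drive_signals(c(0, 0.1, 0.15), p_rcmus = 1), "constant step")
  expect_error(drive_signals(0.5), "length")
})

test_that("equilibrium: zero drives and zero init stay at rest", {
  tr <- simulate_mechanics(mech_params(),
                           drive_signals(seq(0, 2, by = 0.01)))
  expect_true(all(tr$v_rc == 0 & tr$v_ab == 0 & tr$v_l == 0))
})
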