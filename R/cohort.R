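#' Virtual participant profile
#'
#' Bundles everything needed to generate a participant's synthetic
#' recordings: mechanical parameters, breathing pattern, and the additive
#' Gaussian noise levels of the two measurement surrogates (M-mode
#' displacement and spirometer flow).
#'
#' @param params A [mech_params()] object.
#' @param pattern A [breath_pattern()] object.
#' @param noise_disp Displacement noise SD, cm (>= 0).
#' @param noise_flow Flow noise SD, L/s (>= 0).
#' @param id Participant label.
#' @return An object of class `participant_profile`.
#' @export
participant_profile <- function(params = mech_params(),
                                pattern = breath_pattern(),
                                noise_disp = 0.05, noise_flow = 0.02,
                                id = "P1") {
  if (noise_disp < 0 || noise_flow < 0) abort("noise SDs must be >= 0")
  structure(list(params = as_mech_params(params), pattern = pattern,
                 noise_disp = noise_disp, noise_flow = noise_flow,
                 id = as.character(id)),
            class = "participant_profile")
}

#' Sample a cohort of virtual participants
#'
#' Draws `n` participant profiles around the reference mechanics: every
#' resistance and compliance is the reference value times an independent
#' lognormal factor with unit mean and coefficient of variation `cv`
#' (keeping all parameters positive), and breath periods are uniform on
#' 3-6 s. Deterministic given the seed; `cv = 0` reproduces the reference
#' parameters exactly.
#'
#' @param n Cohort size (>= 1).
#' @param seed Integer RNG seed.
#' @param cv Coefficient of variation of the lognormal factors (>= 0).
#' @param noise_disp,noise_flow Measurement noise SDs passed to every
#'   profile.
#' @return List of [participant_profile()] objects.
#' @export
sample_cohort <- function(n, seed, cv = 0.2,
                          noise_disp = 0.05, noise_flow = 0.02) {
  if (n < 1) abort("`n` must be >= 1")
  if (cv < 0) abort("`cv` must be >= 0")
  base <- mech_params()
  mech_names <- c("r_rc", "r_ab", "r_l", "c_rc", "c_ab", "c_l", "c_pl")
  sdlog <- sqrt(log(1 + cv^2))
  with_seed(seed, {
    purrr::map(seq_len(n), function(i) {
      p <- unclass(base)
      if (cv > 0) {
        fac <- rlnorm(length(mech_names), meanlog = -sdlog^2 / 2, sdlog = sdlog)
        p[mech_names] <- purrr::map2(p[mech_names], fac, `*`)
      }
      period <- runif(1, 3, 6)
      participant_profile(
        params = do.call(mech_params, p),
        pattern = breath_pattern(t_total = period),
        noise_disp = noise_disp, noise_flow = noise_flow,
        id = sprintf("P%d", i))
    })
  })
}

#' Generate a synthetic measurement session
#'
#' Builds the drive traces for the profile (muscle channels always, robotic
#' channel only for the assisted condition), simulates the coupled model,
#' and derives the two measurement surrogates on the shared session grid:
#' displacement = diaphragm displacement plus Gaussian noise, flow = first
#' difference of the lung volume divided by the sample period plus Gaussian
#' noise. The noiseless trajectory is retained as `truth` for oracle testing
#' only.
#'
#' @param profile A [participant_profile()].
#' @param condition `"spontaneous"` or `"assisted"`.
#' @param program A [robot_program()]; required when assisted.
#' @param n_breaths Number of breaths (>= 3).
#' @param seed Integer RNG seed for the measurement noise.
#' @param fs Session sampling rate, Hz (displacement and flow share it).
#' @param pattern Optional [breath_pattern()] override (e.g. the re-solved
#'   assisted-condition pattern); defaults to the profile's.
#' @return A tibble of class `session_recording` with columns `t`,
#'   `displacement` (cm), `flow` (L/s); attributes `condition`, `truth`
#'   (the noiseless [simulate_mechanics()] trajectory), `profile`,
#'   `pattern`, `program`, `fs`.
#' @export
generate_session <- function(profile, condition = c("spontaneous", "assisted"),
                             program = NULL, n_breaths = 6, seed = 1,
                             fs = 100, pattern = NULL) {
  condition <- match.arg(condition)
  if (n_breaths < 3) abort("`n_breaths` must be >= 3")
  if (condition == "assisted" && is.null(program)) {
    abort("assisted condition requires a robot `program`")
  }
  pattern <- pattern %||% profile$pattern
  drives <- build_drives(pattern,
                         program = if (condition == "assisted") program,
                         n_breaths = n_breaths, fs = fs)
  truth <- simulate_mechanics(profile$params, drives,
                              dt = min(1e-3, 1 / fs))
  h <- 1 / fs
  flow_true <- c(diff(truth$v_l), 0) / h
  flow_true[length(flow_true)] <- flow_true[length(flow_true) - 1L]
  n <- nrow(truth)
  noise <- with_seed(seed, list(
    disp = rnorm(n, 0, profile$noise_disp),
    flow = rnorm(n, 0, profile$noise_flow)
  ))
  out <- tibble::tibble(
    t = truth$t,
    displacement = truth$x_di + noise$disp,
    flow = flow_true + noise$flow
  )
  class(out) <- c("session_recording", class(out))
  attr(out, "condition") <- condition
  attr(out, "truth") <- truth
  attr(out, "profile") <- profile
  attr(out, "pattern") <- pattern
  attr(out, "program") <- if (condition == "assisted") program
  attr(out, "fs") <- fs
  out
}

#' Measure a session with the standard pipeline
#'
#' Applies the standard measurement conditioning -- a short centered
#' moving-average (default 0.25 s) that stands in for the smoothing any
#' M-mode reading or spirometry software applies -- then segments the flow
#' trace (zero-crossing with hysteresis) for tidal volume and the
#' displacement trace (separated minima) for excursion, and reports the
#' per-condition means that enter all downstream comparisons. Excursions
#' are read from the smoothed displacement (a raw per-cycle max - min would
#' be biased upward by measurement noise); tidal volumes integrate the raw
#' flow, where noise averages out.
#'
#' @param recording A [generate_session()] result (or any tibble with `t`,
#'   `displacement`, `flow` plus `fs` and `pattern` attributes).
#' @param smooth_s Conditioning window, s (0 disables).
#' @return One-row tibble: `mean_excursion` (cm), `mean_vt` (L),
#'   `n_breaths_disp`, `n_breaths_flow`.
#' @export
measure_session <- function(recording, smooth_s = 0.25) {
  fs <- attr(recording, "fs")
  pattern <- attr(recording, "pattern")
  disp <- smooth_trace(recording$displacement, fs, smooth_s)
  flow_s <- smooth_trace(recording$flow, fs, smooth_s)
  seg_d <- segment_breaths(disp, "displacement",
                           fs = fs, period = pattern$t_total)
  seg_f <- segment_breaths(flow_s, "flow", fs = fs)
  exc <- excursions(disp, seg_d)
  vt <- tidal_volumes(recording$flow, seg_f, dt = 1 / fs)
  tibble::tibble(mean_excursion = mean(exc$excursion),
                 mean_vt = mean(vt$vt),
                 n_breaths_disp = nrow(exc),
                 n_breaths_flow = nrow(vt))
}

#' Calibrate muscle amplitudes to measured targets
#'
#' Solves for the diaphragm and rib-cage muscle amplitudes so that the
#' profile's noiseless spontaneous session reproduces a target mean
#' excursion and mean tidal volume (the printed reference spontaneous
#' values, 1.14 cm and 0.83 L, by default). Because the abdominal
#' compartment responds only to the diaphragm channel, the diaphragm
#' amplitude follows exactly from linearity of the excursion; the rib-cage
#' amplitude is then found by a one-dimensional root search on the residual
#' tidal-volume target.
#'
#' @param profile A [participant_profile()].
#' @param target_vt Target mean tidal volume, L (> 0).
#' @param target_excursion Target mean excursion, cm (> 0).
#' @param n_breaths,fs Session layout used for the calibration measurement.
#' @param bounds Admissible amplitude range, cmH2O.
#' @param on_infeasible What to do when the excursion target alone already
#'   displaces more lung volume than the tidal-volume target asks for:
#'   `"error"` (default) rejects the target pair, `"floor"` accepts a
#'   diaphragm-dominant breather with `a_rc = 0` (used by cohort
#'   generation, where sampled mechanics can make some target pairs
#'   unattainable).
#' @return The profile with its pattern amplitudes (`a_rc`, `a_dim`)
#'   replaced by the calibrated values.
#' @export
calibrate_amplitudes <- function(profile, target_vt = 0.83,
                                 target_excursion = 1.14,
                                 n_breaths = 6, fs = 100,
                                 bounds = c(0, 50),
                                 on_infeasible = c("error", "floor")) {
  on_infeasible <- match.arg(on_infeasible)
  if (target_vt <= 0 || target_excursion <= 0) abort("targets must be > 0")
  pat <- profile$pattern
  sess <- function(a_rc, a_dim) {
    pr <- profile
    pr$noise_disp <- 0; pr$noise_flow <- 0
    pr$pattern <- breath_pattern(pat$t_total, pat$f_insp, a_rc, a_dim)
    generate_session(pr, "spontaneous", n_breaths = n_breaths, seed = 0, fs = fs)
  }
  # diaphragm amplitude: excursion is exactly linear in a_dim (a_rc plays no role)
  e_unit <- measure_session(sess(0, 1))$mean_excursion
  a_dim <- target_excursion / e_unit
  if (a_dim < bounds[1L] || a_dim > bounds[2L]) {
    abort(sprintf("excursion target needs a_dim = %.2f cmH2O, outside [%g, %g]",
                  a_dim, bounds[1L], bounds[2L]))
  }
  vt_of <- function(a_rc) measure_session(sess(a_rc, a_dim))$mean_vt - target_vt
  lo <- vt_of(bounds[1L])
  if (lo > 0 && on_infeasible == "floor") {
    a_rc <- bounds[1L]
  } else {
    hi <- vt_of(bounds[2L])
    if (lo > 0 || hi < 0) {
      abort("tidal-volume target unattainable within the rib-cage amplitude bounds")
    }
    a_rc <- stats::uniroot(vt_of, bounds, tol = 1e-9)$root
  }
  profile$pattern <- breath_pattern(pat$t_total, pat$f_insp, a_rc, a_dim)
  profile
}

#' Calibrate the assisted condition to target effect ratios
#'
#' Explicit calibration knobs for the assisted/spontaneous effect size of a
#' synthetic cohort (not a model prediction): scales the actuator-to-abdomen
#' transmission gain so the assisted mean excursion is `r_disp` times the
#' spontaneous one, then re-solves the assisted-condition rib-cage amplitude
#' so the assisted mean tidal volume is `r_vol` times the spontaneous one
#' (breathing genuinely changes under assistance, so the assisted pattern is
#' allowed to differ).
#'
#' @param profile A calibrated [participant_profile()].
#' @param program A [robot_program()] whose `k_transmission` is rescaled.
#' @param r_disp Target assisted/spontaneous mean-excursion ratio.
#' @param r_vol Target assisted/spontaneous mean-tidal-volume ratio.
#' @param n_breaths,fs Session layout used for calibration.
#' @return List with `program` (rescaled gain), `pattern` (assisted-condition
#'   breath pattern) and the spontaneous reference measures `spont`.
#' @export
calibrate_assistance <- function(profile, program = robot_program(),
                                 r_disp = 1.95, r_vol = 2.14,
                                 n_breaths = 6, fs = 100) {
  if (r_disp <= 0 || r_vol <= 0) abort("ratio targets must be > 0")
  noiseless <- profile
  noiseless$noise_disp <- 0; noiseless$noise_flow <- 0
  spont <- measure_session(
    generate_session(noiseless, "spontaneous", n_breaths = n_breaths,
                     seed = 0, fs = fs))
  # assisted breathing locks onto the robot cycle (synchronization training):
  # the period stretches so the programmed inflation fits the expiration
  pat <- profile$pattern
  t_assist <- max(pat$t_total, program$t_inflate / (1 - pat$f_insp))
  assisted <- function(k, a_rc) {
    prog <- program; prog$k_transmission <- k
    pat2 <- breath_pattern(t_assist, pat$f_insp, a_rc, pat$a_dim)
    measure_session(generate_session(noiseless, "assisted", program = prog,
                                     n_breaths = n_breaths, seed = 0,
                                     fs = fs, pattern = pat2))
  }
  exc_of <- function(k) {
    assisted(k, profile$pattern$a_rc)$mean_excursion - r_disp * spont$mean_excursion
  }
  k <- stats::uniroot(exc_of, c(0, 2), tol = 1e-8, extendInt = "upX")$root
  vt_of <- function(a_rc) {
    assisted(k, a_rc)$mean_vt - r_vol * spont$mean_vt
  }
  # when the robot alone already displaces more lung volume than the target
  # asks for, the closest attainable assisted pattern has no rib-cage drive
  a_rc <- if (vt_of(0) > 0) 0 else stats::uniroot(vt_of, c(0, 50), tol = 1e-9)$root
  program$k_transmission <- k
  list(program = program,
       pattern = breath_pattern(t_assist, pat$f_insp, a_rc, pat$a_dim),
       spont = spont)
}
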