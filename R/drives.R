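#' Time-aligned driving pressure traces
#'
#' Bundles the three driving pressures of the coupled model on a common
#' uniform time grid: rib-cage inspiratory muscle pressure, diaphragm muscle
#' pressure, and the effective extracorporeal robotic pressure on the
#' abdominal wall. The robotic trace is conventionally negative during
#' expiratory assistance (the robot pushes the abdominal wall inward, i.e.
#' the diaphragm cranially) while the abdominal driving pressure remains the
#' plain sum of the diaphragm and robot channels.
#'
#' @param t Strictly increasing, uniformly spaced time grid (s), length >= 2.
#' @param p_rcmus,p_dimus,p_rex Pressure traces (cmH2O) on the same grid.
#' @return A tibble of class `drive_signals` with columns
#'   `t`, `p_rcmus`, `p_dimus`, `p_rex`.
#' @export
drive_signals <- function(t, p_rcmus = 0, p_dimus = 0, p_rex = 0) {
  check_finite(t, "t")
  n <- length(t)
  if (n < 2L) abort("`t` must have length >= 2")
  dt <- diff(t)
  h <- dt[1L]
  if (h <= 0 || any(abs(dt - h) > 1e-9 * max(abs(h), 1))) {
    abort("`t` must be strictly increasing with a constant step")
  }
  recycle <- function(x, name) {
    check_finite(x, name)
    if (length(x) == 1L) x <- rep(x, n)
    if (length(x) != n) abort(sprintf("`%s` must have length 1 or length(t)", name))
    x
  }
  out <- tibble::tibble(
    t = as.numeric(t),
    p_rcmus = recycle(p_rcmus, "p_rcmus"),
    p_dimus = recycle(p_dimus, "p_dimus"),
    p_rex = recycle(p_rex, "p_rex")
  )
  class(out) <- c("drive_signals", class(out))
  out
}

drive_step <- function(drives) drives$t[2L] - drives$t[1L]

#' Breathing pattern of a (virtual) participant
#'
#' Defines the timing and muscle-pressure amplitudes of a periodic breath:
#' period `t_total`, inspiratory fraction `f_insp`, and the peak amplitudes
#' of the rib-cage and diaphragm muscle half-sine drives. The healthy adult
#' respiratory cycle typically lasts 3-6 s; periods outside that range are
#' accepted with a warning.
#'
#' @param t_total Breath period, s.
#' @param f_insp Inspiratory fraction of the cycle, in (0, 1).
#' @param a_rc Rib-cage muscle pressure amplitude, cmH2O (>= 0).
#' @param a_dim Diaphragm muscle pressure amplitude, cmH2O (>= 0).
#' @return An object of class `breath_pattern`.
#' @export
breath_pattern <- function(t_total = 6, f_insp = 0.5, a_rc = 5, a_dim = 2.5) {
  check_positive_scalar(t_total, "t_total")
  check_finite(f_insp, "f_insp")
  if (f_insp <= 0 || f_insp >= 1) abort("`f_insp` must lie in (0, 1)")
  if (a_rc < 0 || a_dim < 0) abort("amplitudes must be >= 0")
  if (t_total < 3 || t_total > 6) {
    warn(sprintf("breath period %g s is outside the typical 3-6 s range", t_total))
  }
  structure(list(t_total = t_total, f_insp = f_insp, a_rc = a_rc, a_dim = a_dim),
            class = "breath_pattern")
}

#' Robotic pressurization program
#'
#' Shape and level of the actuator pressurization applied during expiration.
#' The actuator set pressure is in kPa (the study range is 30-50 kPa); the
#' transmission gain `k_transmission` converts the actuator pressure into
#' the effective abdominal-wall pressure of the model (cmH2O per kPa), so
#' the default 0.1 maps a 30 kPa square program onto a 3 cmH2O effective
#' plateau. Inflation lasts `t_inflate` seconds of each expiratory phase
#' (3 s in the study protocol).
#'
#' @param shape One of `"square"`, `"triangle"`, `"sine"`.
#' @param level_kpa Actuator set pressure, kPa (>= 0).
#' @param k_transmission Actuator-to-abdomen pressure gain, cmH2O/kPa.
#' @param t_inflate Inflation duration within each expiration, s (> 0).
#' @return An object of class `robot_program`.
#' @export
robot_program <- function(shape = c("square", "triangle", "sine"),
                          level_kpa = 30, k_transmission = 0.1,
                          t_inflate = 3) {
  shape <- match.arg(shape)
  check_finite(level_kpa, "level_kpa")
  if (level_kpa < 0) abort("`level_kpa` must be >= 0")
  check_positive_scalar(t_inflate, "t_inflate")
  check_finite(k_transmission, "k_transmission")
  if (k_transmission < 0) abort("`k_transmission` must be >= 0")
  structure(list(shape = shape, level_kpa = level_kpa,
                 k_transmission = k_transmission, t_inflate = t_inflate),
            class = "robot_program")
}

#' Muscle driving pressure trace
#'
#' Half-rectified sine per channel: within each breath the selected muscle
#' channel follows a half-sine of the channel amplitude over the inspiratory
#' window `[0, f_insp * t_total)` and is zero during expiration. The trace is
#' periodic with the breath period.
#'
#' @param pattern A [breath_pattern()].
#' @param t_grid Time grid, s (non-empty).
#' @param channel `"rc"` (rib cage) or `"di"` (diaphragm).
#' @return Numeric pressure trace, cmH2O.
#' @export
muscle_wave <- function(pattern, t_grid, channel = c("rc", "di")) {
  channel <- match.arg(channel)
  if (length(t_grid) == 0L) abort("`t_grid` must be non-empty")
  check_finite(t_grid, "t_grid")
  amp <- if (channel == "rc") pattern$a_rc else pattern$a_dim
  t_insp <- pattern$f_insp * pattern$t_total
  phase <- t_grid %% pattern$t_total
  ifelse(phase < t_insp, amp * sin(pi * phase / t_insp), 0)
}

#' Robotic pressure trace
#'
#' Expiratory-phase robotic assistance: zero during inspiration, and a
#' signed (negative) pressure of the programmed shape during the first
#' `t_inflate` seconds of each expiration. The magnitude is
#' `k_transmission * level_kpa` at the shape's unit peak: a square plateau, a
#' symmetric triangle, or a half-sine over the inflation window. The negative
#' sign encodes the robot pushing the abdominal wall inward (diaphragm
#' cranially) while the abdominal driving pressure stays the plain sum of
#' its two channels.
#'
#' @param program A [robot_program()].
#' @param pattern A [breath_pattern()]; `t_inflate` must fit inside the
#'   expiratory window `(1 - f_insp) * t_total`.
#' @param t_grid Time grid, s.
#' @return Numeric pressure trace, cmH2O (<= 0 everywhere).
#' @export
robot_wave <- function(program, pattern, t_grid) {
  if (length(t_grid) == 0L) abort("`t_grid` must be non-empty")
  check_finite(t_grid, "t_grid")
  t_exp <- (1 - pattern$f_insp) * pattern$t_total
  if (program$t_inflate > t_exp + 1e-12) {
    abort(sprintf("t_inflate (%g s) exceeds the expiratory window (%g s)",
                  program$t_inflate, t_exp))
  }
  t_insp <- pattern$f_insp * pattern$t_total
  phase <- t_grid %% pattern$t_total
  s <- (phase - t_insp) / program$t_inflate   # normalized inflation phase
  active <- phase >= t_insp & s < 1
  unit <- numeric(length(t_grid))
  sa <- s[active]
  unit[active] <- switch(program$shape,
    square = 1,
    triangle = 1 - abs(2 * sa - 1),
    sine = sin(pi * sa)
  )
  -program$k_transmission * program$level_kpa * unit
}

#' Build the full drive set for a breath pattern
#'
#' Convenience wrapper: evaluates both muscle channels and (optionally) the
#' robotic channel on a uniform grid covering `n_breaths` periods at
#' sampling rate `fs`.
#'
#' @param pattern A [breath_pattern()].
#' @param program A [robot_program()] or `NULL` for spontaneous breathing.
#' @param n_breaths Number of breath periods to cover.
#' @param fs Sampling rate, Hz.
#' @return A [drive_signals()] tibble.
#' @export
build_drives <- function(pattern, program = NULL, n_breaths = 6, fs = 100) {
  n <- round(n_breaths * pattern$t_total * fs)
  t <- seq(0, by = 1 / fs, length.out = n + 1L)
  p_rex <- if (is.null(program)) 0 else robot_wave(program, pattern, t)
  drive_signals(t,
                p_rcmus = muscle_wave(pattern, t, "rc"),
                p_dimus = muscle_wave(pattern, t, "di"),
                p_rex = p_rex)
}

#' Pre-folding angle from the origami closure condition
#'
#' For a closed cylindrical fold pattern of tessellated trapezoids with base
#' angle `gamma` and `m` trapezoids around the circumference, the closure
#' condition `tan(gamma) * cos(theta / 2) = tan(pi / m)` fixes the
#' pre-folding angle `theta`. Solves for `theta` in degrees; no closed
#' solution exists when `tan(pi / m) > tan(gamma)`.
#'
#' @param gamma Trapezoid base angle, degrees, in (0, 90).
#' @param m Number of horizontal trapezoids around the tube, integer >= 3.
#' @return Pre-folding angle theta, degrees.
#' @examples
#' yoshimura_prefold_angle(60, 4)  # ~109.47 degrees
#' @export
yoshimura_prefold_angle <- function(gamma, m) {
  check_finite(gamma, "gamma")
  if (gamma <= 0 || gamma >= 90) abort("`gamma` must lie in (0, 90) degrees")
  if (m < 3 || m != round(m)) abort("`m` must be an integer >= 3")
  ratio <- tan(pi / m) / tan(gamma * pi / 180)
  if (ratio > 1) {
    abort(sprintf(
      "no closed solution: tan(pi/%d) exceeds tan(%g deg)", as.integer(m), gamma))
  }
  2 * acos(ratio) * 180 / pi
}
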