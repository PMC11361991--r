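#' One step of the on-off valve control law
#'
#' The supply/exhaust solenoid pair is driven by a dead-band (bang-bang)
#' rule around the target: below `target - threshold` the supply valve opens
#' to inflate, above `target + threshold` the exhaust valve opens to vent,
#' and inside the band both valves close to hold pressure. The two valves
#' are never open simultaneously.
#'
#' @param measured Measured actuator pressure, kPa.
#' @param target Target pressure, kPa.
#' @param threshold Dead-band half-width, kPa (> 0).
#' @return Named logical vector `c(supply =, exhaust =)`.
#' @export
control_step <- function(measured, target, threshold) {
  check_finite(measured, "measured")
  check_finite(target, "target")
  check_positive_scalar(threshold, "threshold")
  supply <- measured < target - threshold
  exhaust <- measured > target + threshold
  c(supply = supply, exhaust = exhaust)
}

#' First-order pneumatic plant parameters
#'
#' A single actuator chamber filled from a constant-pressure source and
#' vented to atmosphere, each path first-order with its own time constant.
#' This is the plant the valve controller is exercised against; it is a
#' simulation construct, not a fitted hardware model.
#'
#' @param tau_fill Inflation time constant, s.
#' @param tau_vent Deflation time constant, s.
#' @param p_supply Source pressure, kPa; must exceed any commanded target.
#' @return An object of class `plant_params`.
#' @export
plant_params <- function(tau_fill = 0.25, tau_vent = 0.35, p_supply = 100) {
  check_positive_scalar(tau_fill, "tau_fill")
  check_positive_scalar(tau_vent, "tau_vent")
  check_positive_scalar(p_supply, "p_supply")
  structure(list(tau_fill = tau_fill, tau_vent = tau_vent,
                 p_supply = p_supply), class = "plant_params")
}

#' Simulate the closed-loop pneumatic system
#'
#' Runs the dead-band valve law against the first-order plant at a fixed
#' control-loop period. Within each period the chamber pressure follows the
#' exact exponential of the active path (fill toward `p_supply`, vent toward
#' 0, or hold). The target may be a constant or a reference trace sampled at
#' the loop rate; the default threshold is 10% of the instantaneous target.
#'
#' @param plant A [plant_params()] object.
#' @param target Constant target (kPa) or a numeric reference trace sampled
#'   every `dt`.
#' @param duration Simulation length, s (used when `target` is constant).
#' @param dt Control-loop period, s (default 0.01, i.e. 100 Hz).
#' @param threshold Dead-band half-width, kPa, or `NULL` for 10% of the
#'   instantaneous target (floored at 0.5 kPa so a zero target still has a
#'   band).
#' @param p0 Initial chamber pressure, kPa.
#' @return A tibble of class `pneumatic_trace` with columns `t`, `pressure`,
#'   `target`, `supply`, `exhaust`.
#' @export
simulate_pneumatics <- function(plant, target, duration = NULL, dt = 0.01,
                                threshold = NULL, p0 = 0) {
  check_positive_scalar(dt, "dt")
  if (length(target) == 1L) {
    if (is.null(duration)) abort("`duration` is required for a constant target")
    if (duration < dt) abort("`duration` must be >= dt")
    n <- as.integer(round(duration / dt))
    target <- rep(as.numeric(target), n + 1L)
  } else {
    n <- length(target) - 1L
    if (n < 1L) abort("reference trace must have length >= 2")
  }
  check_finite(target, "target")
  if (max(target) >= plant$p_supply) {
    abort("`p_supply` must exceed the commanded target")
  }
  thr <- if (is.null(threshold)) pmax(0.1 * abs(target), 0.5) else {
    check_positive_scalar(threshold, "threshold")
    rep(threshold, n + 1L)
  }
  a_fill <- exp(-dt / plant$tau_fill)
  a_vent <- exp(-dt / plant$tau_vent)
  pressure <- numeric(n + 1L)
  supply <- exhaust <- logical(n + 1L)
  pressure[1L] <- p0
  for (i in seq_len(n)) {
    p <- pressure[i]
    sup <- p < target[i] - thr[i]
    exh <- p > target[i] + thr[i]
    supply[i] <- sup
    exhaust[i] <- exh
    pressure[i + 1L] <- if (sup) {
      plant$p_supply + (p - plant$p_supply) * a_fill
    } else if (exh) {
      p * a_vent
    } else p
  }
  out <- tibble::tibble(
    t = seq(0, by = dt, length.out = n + 1L),
    pressure = pressure, target = target,
    supply = supply, exhaust = exhaust
  )
  class(out) <- c("pneumatic_trace", class(out))
  out
}

#' Step-response metrics of a pressure trace
#'
#' For a step experiment from 0 to a constant target: `rise_time` is the
#' first time the trace comes within 10% of the target, `settling_time` is
#' the first time after which the trace never leaves the +/-10%-of-target
#' band, and `overshoot` is how far the maximum exceeds the target (floored
#' at 0). A trace that never reaches the band reports `NA` for the times.
#'
#' @param trace A `pneumatic_trace` tibble or numeric pressure trace (kPa).
#' @param target Constant target pressure, kPa (> 0); taken from the trace
#'   when omitted.
#' @param dt Sample period, s (taken from the trace when omitted).
#' @return A one-row tibble with `rise_time_s`, `settling_time_s`,
#'   `overshoot_kpa`.
#' @export
step_metrics <- function(trace, target = NULL, dt = NULL) {
  if (inherits(trace, "pneumatic_trace")) {
    target <- target %||% trace$target[length(trace$target)]
    dt <- dt %||% (trace$t[2L] - trace$t[1L])
    trace <- trace$pressure
  }
  check_finite(trace, "trace")
  check_positive_scalar(target, "target")
  check_positive_scalar(dt, "dt")
  band <- 0.1 * target
  inside <- abs(trace - target) <= band
  t_of <- function(i) (i - 1L) * dt
  rise <- if (any(inside)) t_of(which(inside)[1L]) else NA_real_
  settle <- NA_real_
  if (any(inside)) {
    outside <- which(!inside)
    settle <- if (length(outside) == 0L) 0 else if (max(outside) < length(trace)) {
      t_of(max(outside) + 1L)
    } else NA_real_
  }
  tibble::tibble(rise_time_s = rise, settling_time_s = settle,
                 overshoot_kpa = max(0, max(trace) - target))
}

#' Mean absolute tracking error
#'
#' Mean of the absolute difference between a measured pressure trace and its
#' reference, the waveform-tracking figure of merit of the pneumatic system.
#'
#' @param trace,reference Equal-length numeric traces, kPa.
#' @return MAE, kPa.
#' @export
tracking_mae <- function(trace, reference) {
  check_finite(trace, "trace")
  check_finite(reference, "reference")
  if (length(trace) != length(reference)) {
    abort("`trace` and `reference` must have equal length")
  }
  mean(abs(trace - reference))
}

#' Reference pressurization waveform in kPa
#'
#' Builds the periodic actuator reference (square, triangle or sine over the
#' inflation window of each breath, zero while deflated) sampled at the
#' control-loop rate, for waveform-tracking experiments. This is the
#' unsigned actuator-side counterpart of [robot_wave()].
#'
#' @param program A [robot_program()].
#' @param pattern A [breath_pattern()].
#' @param duration Total duration, s.
#' @param dt Sample period, s.
#' @return Numeric reference trace, kPa (>= 0).
#' @export
reference_wave_kpa <- function(program, pattern, duration, dt = 0.01) {
  t <- seq(0, duration, by = dt)
  unit <- robot_wave(robot_program(program$shape, program$level_kpa,
                                   k_transmission = 1,
                                   t_inflate = program$t_inflate),
                     pattern, t)
  -unit
}
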