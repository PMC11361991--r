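#' Instantaneous compartment volume derivatives
#'
#' Right-hand side of the coupled two-compartment model. Each chest-wall
#' compartment is a first-order resistance-compliance element driven by its
#' muscle (and, for the abdomen, robotic) pressure; the lung is driven by
#' the pleural pressure generated by the combined rib-cage and abdominal
#' volume change:
#' \deqn{\dot V_{rc} = (P_{rcmus} - V_{rc}/C_{rc})/R_{rc}}
#' \deqn{\dot V_{ab} = (P_{dimus} + P_{rex} - V_{ab}/C_{ab})/R_{ab}}
#' \deqn{\dot V_l = ((V_{ab}+V_{rc})/C_{pl} - V_l/C_l)/R_l}
#'
#' @param v_rc,v_ab,v_l Compartment volume deviations from baseline, L.
#' @param p_rcmus,p_dimus,p_rex Driving pressures, cmH2O.
#' @param params A [mech_params()] object.
#' @return Named numeric vector `c(dv_rc, dv_ab, dv_l)`, L/s.
#' @export
compartment_derivatives <- function(v_rc, v_ab, v_l,
                                    p_rcmus, p_dimus, p_rex, params) {
  args <- list(v_rc = v_rc, v_ab = v_ab, v_l = v_l,
               p_rcmus = p_rcmus, p_dimus = p_dimus, p_rex = p_rex)
  for (nm in names(args)) check_finite(args[[nm]], nm)
  p <- as_mech_params(params)
  c(dv_rc = (p_rcmus - v_rc / p$c_rc) / p$r_rc,
    dv_ab = (p_dimus + p_rex - v_ab / p$c_ab) / p$r_ab,
    dv_l = ((v_ab + v_rc) / p$c_pl - v_l / p$c_l) / p$r_l)
}

#' Pleural pressure from chest-wall volume change
#'
#' The pleural cavity couples the chest wall to the lung: its pressure
#' deviation is the combined rib-cage and abdominal volume change divided by
#' the pleural compliance.
#'
#' @param v_rc,v_ab Volume deviations, L.
#' @param c_pl Pleural compliance, L/cmH2O (> 0).
#' @return Pleural pressure, cmH2O.
#' @export
pleural_pressure <- function(v_rc, v_ab, c_pl) {
  check_positive_scalar(c_pl, "c_pl")
  (v_ab + v_rc) / c_pl
}

#' Abdominal driving pressure
#'
#' The robot's effective pressure on the abdominal wall adds directly to the
#' diaphragm muscle pressure; direction lives in the sign of the robotic
#' trace, not in the algebra.
#'
#' @param p_dimus Diaphragm muscle pressure, cmH2O.
#' @param p_rex Effective robotic pressure, cmH2O.
#' @return Abdominal driving pressure, cmH2O.
#' @export
abdominal_pressure <- function(p_dimus, p_rex) {
  check_finite(p_dimus, "p_dimus")
  check_finite(p_rex, "p_rex")
  p_dimus + p_rex
}

#' Diaphragm displacement from displaced abdominal volume
#'
#' The inward motion of the ventral abdominal wall displaces an equivalent
#' diaphragmatic volume, so the cranio-caudal diaphragm displacement is the
#' abdominal volume change divided by the body cross-sectional area, with
#' explicit unit conversions (L to m^3, m to cm).
#'
#' @param v_ab Abdominal volume deviation, L.
#' @param a_di Body cross-sectional area, m^2 (> 0).
#' @return Diaphragm displacement, cm.
#' @examples
#' diaphragm_displacement(1.2, 0.08)  # 1.5 cm
#' @export
diaphragm_displacement <- function(v_ab, a_di) {
  check_positive_scalar(a_di, "a_di")
  check_finite(v_ab, "v_ab")
  100 * (v_ab * 1e-3) / a_di
}

#' Closed-form step response of a first-order compartment
#'
#' Analytic solution of `R dV/dt + V/C = P0` from rest: the textbook
#' exponential approach `C P0 (1 - exp(-t / (R C)))`. Serves as the
#' independent oracle for the numerical integrator on single-channel
#' constant drives.
#'
#' @param r Resistance, cmH2O/(L·s) (> 0).
#' @param c_ Compliance, L/cmH2O (> 0).
#' @param p0 Constant driving pressure, cmH2O.
#' @param t Time(s) since the step, s (>= 0).
#' @return Volume deviation, L.
#' @export
step_response_closed_form <- function(r, c_, p0, t) {
  check_positive_scalar(r, "r")
  check_positive_scalar(c_, "c_")
  check_finite(t, "t")
  if (any(t < 0)) abort("`t` must be >= 0")
  c_ * p0 * (1 - exp(-t / (r * c_)))
}

# constant system matrix of the coupled linear ODE
system_matrix <- function(p) {
  matrix(c(-1 / (p$r_rc * p$c_rc), 0, 0,
           0, -1 / (p$r_ab * p$c_ab), 0,
           1 / (p$r_l * p$c_pl), 1 / (p$r_l * p$c_pl), -1 / (p$r_l * p$c_l)),
         nrow = 3, byrow = TRUE)
}

# Exact per-step affine propagator of classical RK4 with drives linear in t
# over each step: x_{n+1} = Phi x_n + G0 u_n + G1 u_{n+1}. Derived by
# collecting the RK4 stage contributions of x, u_n, u_{n+1/2}, u_{n+1} for a
# constant matrix M, with u_{n+1/2} = (u_n + u_{n+1})/2.
rk4_propagator <- function(m, h) {
  i3 <- diag(3)
  m2 <- m %*% m
  m3 <- m2 %*% m
  m4 <- m3 %*% m
  phi <- i3 + h * m + h^2 / 2 * m2 + h^3 / 6 * m3 + h^4 / 24 * m4
  ghalf <- h / 6 * (4 * i3 + 2 * h * m + h^2 / 2 * m2)
  g0 <- h / 6 * (i3 + h * m + h^2 / 2 * m2 + h^3 / 4 * m3) + ghalf / 2
  g1 <- h / 6 * i3 + ghalf / 2
  list(phi = phi, g0 = g0, g1 = g1)
}

#' Simulate the coupled respiratory mechanics model
#'
#' Integrates the two-compartment system with a classical fixed-step
#' 4th-order Runge-Kutta scheme, linearly interpolating the drive traces
#' between grid points. Because the system is linear time-invariant, the
#' per-step RK4 update is an affine map with constant matrices, which is
#' evaluated as three C-level recursive filters; the result is algebraically
#' identical to the literal stage-by-stage RK4 loop. Output is sampled on
#' the drive grid with the pleural pressure, abdominal driving pressure and
#' diaphragm displacement populated.
#'
#' @param params A [mech_params()] object.
#' @param drives A [drive_signals()] tibble.
#' @param init Initial volume deviations `c(v_rc, v_ab, v_l)` in L
#'   (default rest at functional residual capacity).
#' @param dt Integrator step, s; must be positive and no larger than the
#'   drive grid step (the step actually used divides the grid step evenly).
#' @return A tibble of class `resp_trajectory` with columns `t`, `v_rc`,
#'   `v_ab`, `v_l` (L), `p_pl`, `p_ab` (cmH2O), `x_di` (cm).
#' @examples
#' d <- drive_signals(seq(0, 10, by = 0.01), p_rex = 3)
#' traj <- simulate_mechanics(mech_params(), d)
#' tail(traj$v_ab, 1)  # -> C_ab * 3 = 1.2 L
#' @export
simulate_mechanics <- function(params, drives, init = c(0, 0, 0), dt = 1e-3) {
  p <- as_mech_params(params)
  if (!inherits(drives, "drive_signals")) {
    drives <- do.call(drive_signals, as.list(drives[c("t", "p_rcmus", "p_dimus", "p_rex")]))
  }
  check_finite(init, "init")
  if (length(init) != 3L) abort("`init` must have length 3")
  check_positive_scalar(dt, "dt")
  h_grid <- drive_step(drives)
  if (dt > h_grid + 1e-12) abort("`dt` must not exceed the drive grid step")
  n_sub <- max(1L, as.integer(ceiling(h_grid / dt - 1e-9)))
  h <- h_grid / n_sub

  n_grid <- nrow(drives)
  # fine grid with n_sub substeps per drive interval; drives interpolate linearly
  if (n_sub > 1L) {
    idx <- seq_len((n_grid - 1L) * n_sub + 1L)
    frac <- (idx - 1L) / n_sub             # position in drive-grid units
    lo <- pmin(floor(frac) + 1L, n_grid - 1L)
    w <- frac - (lo - 1L)
    interp <- function(x) x[lo] * (1 - w) + x[lo + 1L] * w
    u1 <- interp(drives$p_rcmus) / p$r_rc
    u2 <- (interp(drives$p_dimus) + interp(drives$p_rex)) / p$r_ab
  } else {
    u1 <- drives$p_rcmus / p$r_rc
    u2 <- (drives$p_dimus + drives$p_rex) / p$r_ab
  }

  m <- system_matrix(p)
  pr <- rk4_propagator(m, h)
  nn <- length(u1) - 1L

  step_input <- function(g0_row, g1_row, s1, s2) {
    g0_row[1L] * s1[1:nn] + g0_row[2L] * s2[1:nn] +
      g1_row[1L] * s1[2:(nn + 1L)] + g1_row[2L] * s2[2:(nn + 1L)]
  }
  # rows 1 and 2 are decoupled scalar recursions
  w_rc <- pr$g0[1L, 1L] * u1[1:nn] + pr$g1[1L, 1L] * u1[2:(nn + 1L)]
  v_rc <- c(init[1L], as.numeric(
    filter(w_rc, pr$phi[1L, 1L], method = "recursive", init = init[1L])))
  w_ab <- pr$g0[2L, 2L] * u2[1:nn] + pr$g1[2L, 2L] * u2[2:(nn + 1L)]
  v_ab <- c(init[2L], as.numeric(
    filter(w_ab, pr$phi[2L, 2L], method = "recursive", init = init[2L])))
  # lung row couples to the chest-wall states and drive inputs
  z <- pr$phi[3L, 1L] * v_rc[1:nn] + pr$phi[3L, 2L] * v_ab[1:nn] +
    step_input(pr$g0[3L, 1:2], pr$g1[3L, 1:2], u1, u2)
  v_l <- c(init[3L], as.numeric(
    filter(z, pr$phi[3L, 3L], method = "recursive", init = init[3L])))

  if (n_sub > 1L) {
    keep <- seq(1L, length(v_rc), by = n_sub)
    v_rc <- v_rc[keep]; v_ab <- v_ab[keep]; v_l <- v_l[keep]
  }

  out <- tibble::tibble(
    t = drives$t,
    v_rc = v_rc, v_ab = v_ab, v_l = v_l,
    p_pl = (v_ab + v_rc) / p$c_pl,
    p_ab = drives$p_dimus + drives$p_rex,
    x_di = 100 * (v_ab * 1e-3) / p$a_di
  )
  class(out) <- c("resp_trajectory", class(out))
  attr(out, "params") <- p
  out
}
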