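#' Segment a recording into breath cycles
#'
#' Finds breath-cycle start indices. For a flow trace, cycle starts are the
#' negative-to-positive zero crossings detected with a Schmitt trigger whose
#' hysteresis band is +/-2% of the peak absolute flow (so noise below the
#' band cannot create spurious cycles). For a displacement trace, cycle
#' starts are the local minima that are minimal within a half-period window
#' on either side, enforcing a separation of at least half the nominal
#' breath period.
#'
#' @param trace Numeric flow (L/s) or displacement (cm) trace.
#' @param kind `"flow"` or `"displacement"`.
#' @param fs Sampling rate, Hz.
#' @param period Nominal breath period, s (required for displacement).
#' @return An object of class `breath_segmentation`: list with `boundaries`
#'   (cycle-start sample indices) and `n_cycles`.
#' @export
segment_breaths <- function(trace, kind = c("flow", "displacement"),
                            fs, period = NULL) {
  kind <- match.arg(kind)
  check_finite(trace, "trace")
  check_positive_scalar(fs, "fs")
  n <- length(trace)
  if (kind == "flow") {
    band <- 0.02 * max(abs(trace))
    if (band == 0) abort("no complete cycle: flow trace is constant zero")
    state <- ifelse(trace > band, 1L, ifelse(trace < -band, -1L, 0L))
    nz <- which(state != 0L)
    if (length(nz) == 0L) abort("no complete cycle: flow never leaves the hysteresis band")
    # carry the last non-zero state forward
    idx <- cummax(ifelse(state != 0L, seq_len(n), 0L))
    idx[idx == 0L] <- nz[1L]
    filled <- state[idx]
    switches <- which(filled[-1L] == 1L & filled[-n] == -1L) + 1L
    # refine each switch back to the first non-negative sample of its run
    boundaries <- vapply(switches, function(j) {
      while (j > 1L && trace[j - 1L] >= 0) j <- j - 1L
      j
    }, integer(1))
    boundaries <- unique(boundaries)
  } else {
    if (is.null(period)) abort("`period` is required for displacement segmentation")
    check_positive_scalar(period, "period")
    w <- max(1L, as.integer(round(0.5 * period * fs)))
    # candidate local minima (endpoints included), then greedy selection by
    # depth with a half-period exclusion radius
    left <- c(Inf, trace[-n]); right <- c(trace[-1L], Inf)
    cand <- which(trace <= left & trace <= right)
    cand <- cand[order(trace[cand], cand)]
    kept <- integer(0)
    for (i in cand) {
      if (length(kept) == 0L || all(abs(kept - i) > w)) kept <- c(kept, i)
    }
    boundaries <- sort(kept)
  }
  if (length(boundaries) < 2L) abort("no complete cycle found")
  structure(list(boundaries = as.integer(boundaries),
                 n_cycles = length(boundaries) - 1L),
            class = "breath_segmentation")
}

cycle_indices <- function(seg) {
  b <- seg$boundaries
  purrr::map(seq_len(seg$n_cycles), function(i) b[i]:(b[i + 1L] - 1L))
}

#' Per-breath tidal volume by flow integration
#'
#' Tidal volume of each segmented breath is the trapezoidal time integral of
#' the inspiratory (positive) part of the flow over the cycle, the standard
#' spirometric derivation. The expiratory (negative-part) integral is
#' returned alongside as a mass-balance check.
#'
#' @param flow Flow trace, L/s.
#' @param seg A [segment_breaths()] result.
#' @param dt Sample period, s (> 0).
#' @return Tibble with one row per breath: `breath`, `vt` (L, inspiratory),
#'   `vt_exp` (L, magnitude of the expiratory integral).
#' @export
tidal_volumes <- function(flow, seg, dt) {
  check_positive_scalar(dt, "dt")
  check_finite(flow, "flow")
  purrr::map_dfr(cycle_indices(seg), function(idx) {
    idx <- c(idx, min(idx[length(idx)] + 1L, length(flow)))  # close the cycle
    f <- flow[idx]
    tibble::tibble(vt = trapz_uniform(pmax(f, 0), dt),
                   vt_exp = abs(trapz_uniform(pmin(f, 0), dt)))
  }, .id = "breath") |>
    dplyr::mutate(breath = as.integer(.data$breath), .before = 1L)
}

#' Per-breath diaphragm excursion
#'
#' Excursion of each segmented breath is the peak-to-trough amplitude
#' (max - min) of the displacement trace within the cycle, the quantity read
#' off an M-mode ultrasound trace.
#'
#' @param displacement Displacement trace, cm.
#' @param seg A [segment_breaths()] result.
#' @return Tibble with `breath` and `excursion` (cm).
#' @export
excursions <- function(displacement, seg) {
  check_finite(displacement, "displacement")
  purrr::map_dfr(cycle_indices(seg), function(idx) {
    tibble::tibble(excursion = ptp(displacement[idx]))
  }, .id = "breath") |>
    dplyr::mutate(breath = as.integer(.data$breath), .before = 1L)
}

#' Phase-normalized cycle average
#'
#' Resamples each breath cycle to `n_points` samples over normalized phase
#' [0, 1) by linear interpolation and averages pointwise across the first
#' `n_cycles` cycles (defaults: 20 points over 3 consecutive cycles, the
#' protocol used for comparing diaphragm motion curves across conditions).
#'
#' @param trace Numeric trace.
#' @param seg A [segment_breaths()] result with at least `n_cycles` cycles.
#' @param n_points Samples per normalized cycle.
#' @param n_cycles Number of leading cycles to average.
#' @return Tibble with `phase` (in [0,1)) and `value`, `n_points` rows.
#' @export
normalize_cycles <- function(trace, seg, n_points = 20, n_cycles = 3) {
  check_finite(trace, "trace")
  if (seg$n_cycles < n_cycles) {
    abort(sprintf("segmentation has %d cycles, %d requested",
                  seg$n_cycles, n_cycles))
  }
  phase <- (seq_len(n_points) - 1L) / n_points
  b <- seg$boundaries
  resampled <- purrr::map(seq_len(n_cycles), function(i) {
    idx <- b[i]:b[i + 1L]               # inclusive end for interpolation
    y <- trace[idx]
    approx(x = seq_along(y) - 1L, y = y,
           xout = phase * (length(y) - 1L))$y
  })
  tibble::tibble(phase = phase,
                 value = purrr::reduce(resampled, `+`) / n_cycles)
}

#' Relative amplitude error in percent
#'
#' `100 * |sim - obs| / obs`, the per-channel amplitude agreement measure
#' between a simulated and an observed quantity (e.g. mean excursion or mean
#' tidal volume of a condition).
#'
#' @param sim Simulated amplitude.
#' @param obs Observed amplitude (> 0).
#' @return Percent error.
#' @export
amplitude_error <- function(sim, obs) {
  check_finite(sim, "sim")
  check_finite(obs, "obs")
  if (any(obs <= 0)) abort("`obs` must be > 0")
  100 * abs(sim - obs) / obs
}

#' Normalized root-mean-square error in percent
#'
#' RMSE between two equal-length traces, normalized by the observed trace's
#' peak-to-peak range, in percent.
#'
#' @param sim,obs Equal-length numeric traces; `obs` must not be flat.
#' @return NRMSE, percent.
#' @export
nrmse <- function(sim, obs) {
  check_finite(sim, "sim")
  check_finite(obs, "obs")
  if (length(sim) != length(obs)) abort("`sim` and `obs` must have equal length")
  rng <- ptp(obs)
  if (rng == 0) abort("`obs` has zero peak-to-peak range")
  100 * sqrt(mean((sim - obs)^2)) / rng
}

#' Correlation between excursion and tidal volume
#'
#' Pearson correlation (with its two-sided p-value) between per-breath or
#' per-subject diaphragm excursion and tidal volume, the consistency check
#' that displacement of the diaphragm actually drives ventilation.
#'
#' @param excursion,vt Equal-length numeric vectors, >= 3 pairs, each with
#'   nonzero variance.
#' @return One-row tibble with `r` and `p`.
#' @export
disp_vol_correlation <- function(excursion, vt) {
  check_finite(excursion, "excursion")
  check_finite(vt, "vt")
  if (length(excursion) != length(vt) || length(vt) < 3L) {
    abort("need >= 3 paired observations")
  }
  if (sd(excursion) == 0 || sd(vt) == 0) abort("zero-variance input")
  ct <- cor.test(excursion, vt, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value)
}

#' Paired spontaneous-vs-assisted comparison
#'
#' Summarizes the per-subject effect of robotic assistance: the ratio of
#' condition means, the mean of per-subject ratios, and the two-sided exact
#' Wilcoxon signed-rank p-value on the paired values (exact distribution for
#' cohorts up to 25 subjects; zero differences are dropped, and a fully tied
#' cohort reports p = 1).
#'
#' @param spont,assisted Equal-length (>= 2) per-subject values.
#' @return An object of class `comparison_result`: list with `ratio_means`,
#'   `mean_ratio`, `p_value` and a `pairs` tibble.
#' @export
paired_ratio_test <- function(spont, assisted) {
  check_finite(spont, "spont")
  check_finite(assisted, "assisted")
  n <- length(spont)
  if (n != length(assisted) || n < 2L) abort("need equal-length vectors, n >= 2")
  if (mean(spont) == 0) abort("zero spontaneous mean")
  d <- assisted - spont
  p_value <- if (all(d == 0)) 1 else {
    suppressWarnings(
      wilcox.test(assisted, spont, paired = TRUE, exact = n <= 25)$p.value)
  }
  structure(list(
    ratio_means = mean(assisted) / mean(spont),
    mean_ratio = mean(assisted / spont),
    p_value = p_value,
    pairs = tibble::tibble(subject = seq_len(n), spont = spont,
                           assisted = assisted)
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> n=%d  ratio of means %.3f  mean ratio %.3f  p=%.4g\n",
              nrow(x$pairs), x$ratio_means, x$mean_ratio, x$p_value))
  invisible(x)
}
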