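# shared fixtures; heavy ones are computed lazily and cached per test run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# reference-parameter profile calibrated to the printed spontaneous values
# (mean excursion 1.14 cm, mean tidal volume 0.83 L), noiseless
p6_profile <- function() {
  fixture("p6", calibrate_amplitudes(
    participant_profile(noise_disp = 0, noise_flow = 0, id = "P6")))
}

p6_assist <- function() {
  fixture("p6_assist", calibrate_assistance(p6_profile()))
}

ptp_of <- function(x) max(x) - min(x)

# smooth band-limited random signal on [0, dur] for property tests
random_smooth <- function(dur, fs, n_harmonics = 4, amp = 1) {
  t <- seq(0, dur, by = 1 / fs)
  k <- seq_len(n_harmonics)
  a <- stats::rnorm(n_harmonics) / k
  b <- stats::rnorm(n_harmonics) / k
  y <- rowSums(vapply(k, function(j) {
    a[j] * sin(2 * pi * j * t / dur) + b[j] * cos(2 * pi * j * t / dur)
  }, numeric(length(t))))
  amp * y / max(abs(y), 1e-12)
}
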