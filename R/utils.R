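#' @importFrom rlang abort warn %||%
#' @importFrom stats approx filter median runmed sd cor.test wilcox.test rnorm rlnorm runif
#' @importFrom utils head tail modifyList
NULL

# run `code` under a fixed RNG seed, restoring the caller's RNG state after
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# trapezoidal integral of y over a uniform grid of spacing dt
trapz_uniform <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  dt * (sum(y) - (y[1L] + y[n]) / 2)
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite numeric (got non-finite or missing values)", name))
  }
  invisible(x)
}

check_positive_scalar <- function(x, name) {
  check_finite(x, name)
  if (length(x) != 1L || x <= 0) {
    abort(sprintf("`%s` must be a single strictly positive number", name))
  }
  invisible(x)
}

ptp <- function(x) max(x) - min(x)

# centered moving average over a window of `window_s` seconds; edges use the
# partial window. Identity when the window covers < 2 samples.
smooth_trace <- function(x, fs, window_s) {
  k <- as.integer(round(window_s * fs))
  if (k < 2L) return(x)
  if (k %% 2L == 0L) k <- k + 1L
  n <- length(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
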