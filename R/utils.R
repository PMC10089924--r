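# Internal numeric helpers shared across modules.

# Centered moving average with symmetrically shrinking windows at the edges.
# `window` is the nominal width in samples; the effective centered width is
# 2*floor(window/2)+1 in the interior so the window is always symmetric
# (no phase shift).
moving_average <- function(x, window) {
  n <- length(x)
  half <- floor(window / 2)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  k <- pmin(half, i - 1L, n - i)
  lo <- i - k
  hi <- i + k
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# z-score ignoring NAs; degenerate (zero-variance) input is an error at the
# call sites that need it, callers that tolerate it pass check = FALSE.
zscore <- function(x, check = TRUE) {
  s <- sd(x, na.rm = TRUE)
  if (check && (!is.finite(s) || s == 0)) {
    stop("cannot z-score a constant or empty trace")
  }
  (x - mean(x, na.rm = TRUE)) / s
}

# Linear-interpolation resampling of a uniformly sampled trace to a new rate,
# preserving the wall-clock span [0, (n-1)/rate].
resample_linear <- function(x, rate_in, rate_out) {
  n <- length(x)
  if (n < 2L) return(x)
  t_in <- (seq_len(n) - 1L) / rate_in
  t_out <- seq(0, t_in[n], by = 1 / rate_out)
  approx(t_in, x, xout = t_out, rule = 2)$y
}

#' Gaussian 1/f^beta noise by spectral shaping
#'
#' White noise is shaped in the frequency domain by `f^(-beta/2)` and
#' transformed back, giving a Gaussian trace with power spectral density
#' proportional to `1/f^beta` -- the tonic component of the synthetic
#' norepinephrine signal. Output has zero mean and unit standard
#' deviation.
#'
#' @param n number of samples.
#' @param beta spectral exponent (0 = white, 1 = pink).
#' @param rate sampling rate in Hz (affects only the frequency labeling).
#' @return numeric vector of length `n`.
#' @export
powerlaw_noise <- function(n, beta, rate = 1) {
  nfft <- nextn(n, 2)
  white <- rnorm(nfft)
  spec <- fft(white)
  freqs <- c(0, seq_len(nfft - 1)) * rate / nfft
  # fold to physical frequencies for the amplitude shaping
  freqs <- pmin(freqs, rate - freqs)
  amp <- c(0, freqs[-1]^(-beta / 2))
  shaped <- Re(fft(spec * amp, inverse = TRUE)) / nfft
  out <- shaped[seq_len(n)]
  (out - mean(out)) / sd(out)
}

# Times of a homogeneous Poisson process on [margin, duration - margin].
poisson_times <- function(rate_per_s, duration_s, margin_s = 0) {
  span <- duration_s - 2 * margin_s
  if (span <= 0 || rate_per_s <= 0) return(numeric(0))
  n <- stats::rpois(1, rate_per_s * span)
  sort(runif(n, margin_s, duration_s - margin_s))
}

# Double-exponential (alpha-like) transient kernel sampled at `rate`,
# normalized to unit peak. Rise and decay time constants in seconds.
transient_kernel <- function(rise_s, decay_s, rate, length_s = rise_s + 6 * decay_s) {
  t <- seq(0, length_s, by = 1 / rate)
  k <- (1 - exp(-t / rise_s)) * exp(-t / decay_s)
  k / max(k)
}

# Add unit-peak kernels at event times (seconds) onto a zero trace of n
# samples, scaled by `amplitudes`.
add_transients <- function(n, rate, times_s, amplitudes, kernel) {
  x <- numeric(n)
  lk <- length(kernel)
  for (i in seq_along(times_s)) {
    i0 <- round(times_s[i] * rate) + 1L
    if (i0 > n) next
    i1 <- min(n, i0 + lk - 1L)
    idx <- seq.int(i0, i1)
    x[idx] <- x[idx] + amplitudes[i] * kernel[seq_len(length(idx))]
  }
  x
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (positive && x <= 0)) {
    stop(sprintf("`%s` must be a finite %s scalar", name,
                 if (positive) "positive" else "numeric"))
  }
  invisible(x)
}
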