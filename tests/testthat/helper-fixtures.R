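# Shared fixtures and independent oracles for the test suite.

# Small contaminated movie with known parameters, built directly from the
# model (independent of the generator's session machinery).
make_toy_movie <- function(n_pixels = 9, n_frames = 400, frame_rate = 2,
                           a = NULL, b = NULL, noise_sd = 0,
                           f_const = NULL, seed = 1) {
  set.seed(seed)
  h <- sin(2 * pi * 0.1 * (seq_len(n_frames) - 1) / frame_rate) * 0.3
  h <- h - mean(h)
  if (is.null(a)) a <- runif(n_pixels, 0.1, 0.8)
  if (is.null(b)) b <- rep(0, n_pixels)
  f0 <- if (is.null(f_const)) runif(n_pixels, 50, 100) else rep(f_const, n_pixels)
  f <- matrix(rep(f0, n_frames), n_pixels)
  y <- f * exp(outer(a, h) + b) +
    matrix(rnorm(n_pixels * n_frames, sd = noise_sd), n_pixels)
  side <- round(sqrt(n_pixels))
  list(movie = pixel_movie(y, frame_rate, dim_spatial = c(side, side)),
       f = f, h = h, a = a, b = b)
}

# Direct argmax cross-correlation oracle: plain shift-and-correlate on
# equal-rate vectors, no resampling, no NA handling.
oracle_xcorr_peak_lag <- function(x, y, rate, max_lag_s) {
  max_lag <- round(max_lag_s * rate)
  lags <- seq.int(-max_lag, max_lag)
  n <- length(x)
  rs <- vapply(lags, function(l) {
    if (l <= 0) {
      cor(x[seq_len(n + l)], y[seq.int(1 - l, n)])
    } else {
      cor(x[seq.int(1 + l, n)], y[seq_len(n - l)])
    }
  }, numeric(1))
  lags[which.max(rs)] / rate
}

# Explicit convolution oracle for the centered moving average (interior
# samples only).
oracle_moving_average_interior <- function(x, window) {
  half <- floor(window / 2)
  width <- 2 * half + 1
  as.numeric(stats::filter(x, rep(1 / width, width), sides = 2))
}

# Amplitude of a sinusoid of frequency f in a trace, by projection.
sine_amplitude <- function(x, f, rate) {
  t <- (seq_along(x) - 1) / rate
  2 * sqrt(mean(x * sin(2 * pi * f * t))^2 + mean(x * cos(2 * pi * f * t))^2)
}

default_cfg <- function(seed, duration_s = 600, ...) {
  sim_config(duration_s = duration_s, seed = seed, ...)
}
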