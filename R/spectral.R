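#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` for time-bandwidth
#' product `nw`, the taper family used throughout the spectral module
#' (band power at time-bandwidth 2.5 with 2 tapers, full spectra at 6 with
#' 8 tapers, sensor spectra at 3 with 5 tapers).
#'
#' Tapers are the leading eigenvectors of the symmetric tridiagonal Slepian
#' matrix. For long windows (n > `exact_max`) the tapers are computed on a
#' reduced grid, spline-interpolated to length `n` and re-orthonormalized;
#' the resulting spectral concentration is indistinguishable at the
#' resolutions used here.
#'
#' @param n window length in samples.
#' @param nw time-bandwidth product (dimensionless).
#' @param k number of tapers (at most `2*nw - 1` for well-concentrated
#'   tapers).
#' @param exact_max largest `n` for which the eigenproblem is solved
#'   exactly.
#' @return an `n x k` matrix; columns are orthonormal
#'   (`sum(taper^2) == 1`).
#' @export
dpss_tapers <- function(n, nw, k, exact_max = 1200L) {
  stopifnot_scalar(n, "n")
  stopifnot_scalar(nw, "nw")
  stopifnot_scalar(k, "k")
  n <- as.integer(n)
  k <- as.integer(k)
  if (k >= n) stop("need fewer tapers than samples")
  key <- sprintf("%d_%g_%d", n, nw, k)
  cached <- .dpss_cache[[key]]
  if (!is.null(cached)) return(cached)

  if (n <= exact_max) {
    tapers <- dpss_exact(n, nw, k)
  } else {
    m <- as.integer(exact_max)
    base <- dpss_exact(m, nw, k)
    grid_in <- seq(0, 1, length.out = m)
    grid_out <- seq(0, 1, length.out = n)
    tapers <- apply(base, 2, function(col) {
      stats::spline(grid_in, col, xout = grid_out)$y
    })
    # re-orthonormalize (Gram-Schmidt) to restore exact orthogonality
    for (j in seq_len(k)) {
      v <- tapers[, j]
      if (j > 1L) {
        prev <- tapers[, seq_len(j - 1L), drop = FALSE]
        v <- v - prev %*% crossprod(prev, v)
      }
      tapers[, j] <- v / sqrt(sum(v^2))
    }
  }
  assign(key, tapers, envir = .dpss_cache)
  tapers
}

.dpss_cache <- new.env(parent = emptyenv())

dpss_exact <- function(n, nw, k) {
  w <- nw / n
  i <- seq_len(n) - 1L
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- seq_len(n - 1) * (n - seq_len(n - 1)) / 2
  m <- diag(diag_main)
  m[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  m[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  eig <- eigen(m, symmetric = TRUE)
  tapers <- eig$vectors[, seq_len(k), drop = FALSE]
  # Sign convention: symmetric tapers have positive mean; antisymmetric
  # tapers start with a positive slope.
  for (j in seq_len(k)) {
    s <- sum(tapers[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) tapers[, j] <- -tapers[, j]
    } else if (tapers[2, j] - tapers[1, j] < 0) {
      tapers[, j] <- -tapers[, j]
    }
    tapers[, j] <- tapers[, j] / sqrt(sum(tapers[, j]^2))
  }
  tapers
}

#' Multitaper power spectral density of one window
#'
#' One-sided PSD estimate averaged over DPSS tapers, with no frequency
#' padding. With tapers normalized to unit energy, summing the PSD times
#' the bin width recovers the (demeaned) signal variance, so band-
#' integrated power is comparable to time-domain variance.
#'
#' @param x numeric vector (one analysis window).
#' @param rate sampling rate in Hz.
#' @param nw time-bandwidth product.
#' @param k number of tapers.
#' @param demean subtract the window mean first (default `TRUE`).
#' @return list with `freqs_hz` and `power` (units x^2/Hz).
#' @export
multitaper_psd <- function(x, rate, nw, k, demean = TRUE) {
  n <- length(x)
  if (n < 8L) stop("window too short for spectral estimation")
  if (demean) x <- x - mean(x)
  tapers <- dpss_tapers(n, nw, k)
  spec <- stats::mvfft(tapers * x)
  pow2 <- rowMeans(abs(spec)^2) / rate
  nf <- floor(n / 2) + 1L
  freqs <- (seq_len(nf) - 1L) * rate / n
  pow <- pow2[seq_len(nf)]
  # fold negative frequencies (one-sided); DC and Nyquist are not doubled
  dbl <- seq(2L, nf - if (n %% 2 == 0) 1L else 0L)
  pow[dbl] <- 2 * pow[dbl]
  list(freqs_hz = freqs, power = pow)
}

new_lfp_recording <- function(voltage, rate = 1000, channel = "ipsi",
                              notch_applied = FALSE, detrended = FALSE) {
  if (!all(is.finite(voltage))) stop("LFP trace contains non-finite values")
  structure(
    list(voltage = as.numeric(voltage), rate = rate, channel = channel,
         notch_applied = notch_applied, detrended = detrended),
    class = "lfp_recording"
  )
}

#' Construct an LFP recording object
#'
#' @param voltage voltage trace in microvolts.
#' @param rate sampling rate in Hz (1000 Hz for the recordings modeled
#'   here).
#' @param channel `"ipsi"` or `"contra"`.
#' @export
lfp_recording <- function(voltage, rate = 1000, channel = "ipsi") {
  new_lfp_recording(voltage, rate, channel)
}

as_lfp <- function(x, rate = 1000) {
  if (inherits(x, "lfp_recording")) x else new_lfp_recording(x, rate)
}

#' Preprocess an LFP recording
#'
#' Removes mains interference with a zero-phase second-order IIR notch at
#' 60 Hz (2 Hz stopband) and compensates drifting baselines by subtracting
#' the best-fit line.
#'
#' @param raw an [lfp_recording()] or numeric vector.
#' @param rate sampling rate, used when `raw` is a bare vector.
#' @param notch_hz mains frequency to remove.
#' @param notch_bw_hz stopband width in Hz.
#' @return an `lfp_recording` with preprocessing flags set.
#' @export
preprocess_lfp <- function(raw, rate = 1000, notch_hz = 60, notch_bw_hz = 2) {
  lfp <- as_lfp(raw, rate)
  x <- lfp$voltage
  tt <- seq_along(x)
  fit <- stats::lm.fit(cbind(1, tt), x)
  x <- x - fit$fitted.values
  ny <- lfp$rate / 2
  bs <- signal::butter(2, c(notch_hz - notch_bw_hz / 2,
                            notch_hz + notch_bw_hz / 2) / ny, type = "stop")
  x <- signal::filtfilt(bs, x)
  new_lfp_recording(x, lfp$rate, lfp$channel,
                    notch_applied = TRUE, detrended = TRUE)
}

#' Band-limited power over moving windows
#'
#' Multitaper band power with time-bandwidth 2.5 and two tapers over 5 s
#' moving windows (no frequency padding), integrated over the requested
#' band. Windows are non-overlapping by default; pass `step_s` for
#' overlap.
#'
#' @param lfp an [lfp_recording()] or numeric vector.
#' @param band length-2 numeric, band edges in Hz.
#' @param rate sampling rate if `lfp` is a bare vector.
#' @param window_s analysis window length in seconds.
#' @param step_s step between window starts (defaults to `window_s`).
#' @param nw,k multitaper parameters.
#' @return a `band_power_trace`: data.frame-like list with `times_s`
#'   (window centers) and `power`, plus band/taper metadata.
#' @export
multitaper_bandpower <- function(lfp, band, rate = 1000, window_s = 5,
                                 step_s = window_s, nw = 2.5, k = 2) {
  lfp <- as_lfp(lfp, rate)
  if (length(band) != 2L || band[1] >= band[2]) {
    stop("`band` must be increasing (lo, hi) in Hz")
  }
  if (band[2] > lfp$rate / 2) stop("band extends above the Nyquist frequency")
  nwin <- round(window_s * lfp$rate)
  nstep <- max(1L, round(step_s * lfp$rate))
  n <- length(lfp$voltage)
  if (n < nwin) stop("recording shorter than one analysis window")
  starts <- seq.int(1L, n - nwin + 1L, by = nstep)
  df <- lfp$rate / nwin
  power <- vapply(starts, function(s) {
    psd <- multitaper_psd(lfp$voltage[s:(s + nwin - 1L)], lfp$rate, nw, k)
    sel <- psd$freqs_hz >= band[1] & psd$freqs_hz <= band[2]
    sum(psd$power[sel]) * df
  }, numeric(1))
  structure(
    list(times_s = (starts - 1L + nwin / 2) / lfp$rate, power = power,
         band = band, window_s = window_s, step_s = step_s,
         taper_params = c(nw = nw, k = k)),
    class = "band_power_trace"
  )
}

#' Moving-window multitaper spectrogram
#'
#' @inheritParams multitaper_bandpower
#' @param freq_range optional length-2 limit on returned frequencies.
#' @return a `spectrogram`: `times_s` (window centers), `freqs_hz`, and
#'   `power` (time x frequency matrix), with `normalization = "none"`.
#' @export
multitaper_spectrogram <- function(lfp, rate = 1000, window_s = 1,
                                   step_s = 0.5, nw = 2.5, k = 2,
                                   freq_range = NULL) {
  lfp <- as_lfp(lfp, rate)
  nwin <- round(window_s * lfp$rate)
  nstep <- max(1L, round(step_s * lfp$rate))
  n <- length(lfp$voltage)
  if (n < nwin) stop("recording shorter than one analysis window")
  starts <- seq.int(1L, n - nwin + 1L, by = nstep)
  first <- multitaper_psd(lfp$voltage[seq_len(nwin)], lfp$rate, nw, k)
  keep <- rep(TRUE, length(first$freqs_hz))
  if (!is.null(freq_range)) {
    keep <- first$freqs_hz >= freq_range[1] & first$freqs_hz <= freq_range[2]
  }
  power <- matrix(NA_real_, length(starts), sum(keep))
  power[1, ] <- first$power[keep]
  for (i in seq_along(starts)[-1]) {
    s <- starts[i]
    psd <- multitaper_psd(lfp$voltage[s:(s + nwin - 1L)], lfp$rate, nw, k)
    power[i, ] <- psd$power[keep]
  }
  structure(
    list(times_s = (starts - 1L + nwin / 2) / lfp$rate,
         freqs_hz = first$freqs_hz[keep], power = power,
         window_s = window_s, step_s = step_s,
         taper_params = c(nw = nw, k = k), normalization = "none"),
    class = "spectrogram"
  )
}

#' Event-triggered, median-normalized spectrogram
#'
#' Time-frequency power around event onsets: for each event the
#' spectrogram columns within `window_s` of the onset are collected, the
#' median across events is taken at each (time, frequency) bin, and each
#' frequency row is divided by its own median over the window. The result
#' is dimensionless with per-frequency median exactly 1, so state
#' transitions appear as rows above/below 1 on either side of the event.
#'
#' @param lfp an [lfp_recording()], numeric vector, or a precomputed
#'   [multitaper_spectrogram()] (reuse one spectrogram across many event
#'   sets, e.g. shuffled-onset nulls).
#' @param event_times_s event onsets in seconds.
#' @param window_s half-width of the event window in seconds.
#' @param rate,sub_window_s,step_s,nw,k,freq_range passed to
#'   [multitaper_spectrogram()] when `lfp` is raw data.
#' @return a `spectrogram` with `times_s` relative to the event onset,
#'   `normalization = "per-frequency-median"`, and `n_events` used.
#' @export
event_triggered_spectrogram <- function(lfp, event_times_s, window_s = 5,
                                        rate = 1000, sub_window_s = 1,
                                        step_s = 0.5, nw = 2.5, k = 2,
                                        freq_range = NULL) {
  sg <- if (inherits(lfp, "spectrogram")) {
    lfp
  } else {
    multitaper_spectrogram(lfp, rate = rate, window_s = sub_window_s,
                           step_s = step_s, nw = nw, k = k,
                           freq_range = freq_range)
  }
  step <- sg$times_s[2] - sg$times_s[1]
  rel <- seq(-window_s, window_s, by = step)
  usable <- event_times_s[event_times_s + rel[1] >= sg$times_s[1] &
                          event_times_s + rel[length(rel)] <=
                            sg$times_s[length(sg$times_s)]]
  if (length(usable) == 0L) stop("no events with a full window inside the recording")
  slices <- array(NA_real_, c(length(usable), length(rel), length(sg$freqs_hz)))
  for (i in seq_along(usable)) {
    idx <- round((usable[i] + rel - sg$times_s[1]) / step) + 1L
    slices[i, , ] <- sg$power[idx, ]
  }
  med <- apply(slices, c(2, 3), median)
  row_med <- apply(med, 2, median)
  if (any(row_med <= 0)) stop("zero median power at some frequency; cannot normalize")
  norm <- sweep(med, 2, row_med, "/")
  structure(
    list(times_s = rel, freqs_hz = sg$freqs_hz, power = norm,
         window_s = window_s, taper_params = sg$taper_params,
         normalization = "per-frequency-median", n_events = length(usable)),
    class = "spectrogram"
  )
}

#' Pre/post band-power change around events
#'
#' For each event, the median band power in the `window_s` preceding the
#' onset and the median in the `window_s` following it; the post/pre
#' ratio per event is returned for resampling tests.
#'
#' @param power a [multitaper_bandpower()] result.
#' @param event_times_s event onsets in seconds.
#' @param window_s pre/post window length in seconds.
#' @return data.frame with `event_time_s`, `pre`, `post`, `ratio`
#'   (`NA` marks an undefined ratio from a zero pre-event median).
#' @export
band_change_around_events <- function(power, event_times_s, window_s = 5) {
  if (!inherits(power, "band_power_trace")) stop("`power` must be a band_power_trace")
  res <- lapply(event_times_s, function(t0) {
    pre <- power$power[power$times_s >= t0 - window_s & power$times_s < t0]
    post <- power$power[power$times_s > t0 & power$times_s <= t0 + window_s]
    if (!length(pre) || !length(post)) return(NULL)
    mpre <- median(pre)
    mpost <- median(post)
    data.frame(event_time_s = t0, pre = mpre, post = mpost,
               ratio = if (mpre > 0) mpost / mpre else NA_real_)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no events with full pre/post windows")
  out
}

#' Full-recording multitaper spectrum
#'
#' Average spectrum with time-bandwidth 6 and eight tapers. Total power is
#' the sum over all frequency bins; relative power per requested band is
#' the band sum divided by the total.
#'
#' @param lfp an [lfp_recording()] or numeric vector.
#' @param rate sampling rate if `lfp` is a bare vector.
#' @param bands optional named list of length-2 band edges for relative
#'   power.
#' @param nw,k multitaper parameters.
#' @return a `spectrum_estimate` with `freqs_hz`, `power`, `total_power`,
#'   and `relative_power`.
#' @export
full_spectrum <- function(lfp, rate = 1000, bands = NULL, nw = 6, k = 8) {
  lfp <- as_lfp(lfp, rate)
  psd <- multitaper_psd(lfp$voltage, lfp$rate, nw, k)
  total <- sum(psd$power)
  rel <- NULL
  if (!is.null(bands)) {
    nyq <- max(psd$freqs_hz)
    rel <- vapply(bands, function(b) {
      # half-open [lo, hi) so adjacent bands partition the bins exactly;
      # a band reaching the Nyquist frequency keeps its upper edge
      sel <- psd$freqs_hz >= b[1] &
        (psd$freqs_hz < b[2] | (b[2] >= nyq & psd$freqs_hz <= b[2]))
      sum(psd$power[sel]) / total
    }, numeric(1))
  }
  structure(
    list(freqs_hz = psd$freqs_hz, power = psd$power,
         taper_params = c(nw = nw, k = k), total_power = total,
         relative_power = rel),
    class = "spectrum_estimate"
  )
}

#' Spectrum of a slow sensor trace with a power-law fit
#'
#' The trace is cut into 10 min segments (a short final or only segment is
#' padded with the trace median), each segment gets a multitaper spectrum
#' with time-bandwidth 3 and five tapers (no frequency padding), segments
#' are averaged, and the result is restricted to frequencies in
#' `freq_limits` (default 3e-3 to 0.9 Hz; the upper limit is clipped to
#' the Nyquist frequency with a warning when the frame rate is too low).
#' A power-law exponent is fit by ordinary least squares on log power
#' versus log frequency over the band, excluding the lowest resolvable
#' bin.
#'
#' @param ne sensor fluorescence trace.
#' @param frame_rate acquisition rate in Hz.
#' @param segment_s segment length in seconds.
#' @param freq_limits reporting band in Hz.
#' @param nw,k multitaper parameters.
#' @return a `spectrum_estimate` with additional fields `exponent` (beta
#'   in 1/f^beta, positive for decaying spectra) and `n_segments`.
#' @export
grabne_spectrum <- function(ne, frame_rate, segment_s = 600,
                            freq_limits = c(3e-3, 0.9), nw = 3, k = 5) {
  stopifnot_scalar(frame_rate, "frame_rate")
  nseg <- round(segment_s * frame_rate)
  if (length(ne) < 2L) stop("trace too short")
  pad_value <- median(ne)
  n_segments <- max(1L, ceiling(length(ne) / nseg))
  padded <- c(ne, rep(pad_value, n_segments * nseg - length(ne)))
  hi <- freq_limits[2]
  if (frame_rate / 2 < hi) {
    hi <- frame_rate / 2
    warning("upper frequency limit clipped to the Nyquist frequency")
  }
  acc <- NULL
  for (i in seq_len(n_segments)) {
    seg <- padded[((i - 1L) * nseg + 1L):(i * nseg)]
    psd <- multitaper_psd(seg, frame_rate, nw, k)
    acc <- if (is.null(acc)) psd$power else acc + psd$power
    freqs <- psd$freqs_hz
  }
  power <- acc / n_segments
  sel <- freqs >= freq_limits[1] & freqs <= hi
  freqs <- freqs[sel]
  power <- power[sel]
  fit_sel <- seq_along(freqs) > 1L  # drop the lowest resolvable bin
  fit <- lm(log(power[fit_sel]) ~ log(freqs[fit_sel]))
  structure(
    list(freqs_hz = freqs, power = power, taper_params = c(nw = nw, k = k),
         total_power = sum(power), relative_power = NULL,
         exponent = -unname(coef(fit)[2]), n_segments = n_segments),
    class = "spectrum_estimate"
  )
}
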