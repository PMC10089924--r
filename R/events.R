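#' Filter an astrocyte calcium event table
#'
#' Retains events with area greater than `min_area_um2` (10, in square
#' micrometers), duration of at least `min_frames` (2) frames, and
#' detection significance below `max_p` (0.05). The filter is idempotent
#' and each threshold can only shrink the retained set.
#'
#' @param table data.frame with columns `onset_frame`, `offset_frame`,
#'   `area_um2`, `significance`.
#' @param min_area_um2,min_frames,max_p inclusion thresholds.
#' @return the filtered data.frame.
#' @export
filter_astro_events <- function(table, min_area_um2 = 10, min_frames = 2,
                                max_p = 0.05) {
  needed <- c("onset_frame", "offset_frame", "area_um2", "significance")
  missing <- setdiff(needed, names(table))
  if (length(missing)) {
    stop("event table is missing column(s): ", paste(missing, collapse = ", "))
  }
  dur <- table$offset_frame - table$onset_frame + 1L
  keep <- table$area_um2 > min_area_um2 & dur >= min_frames &
    table$significance < max_p
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Population fluorescence from per-unit traces
#'
#' Each trace is normalized to its own maximum and the frame-wise mean is
#' taken, the definition used for both astrocyte (per-event compensated)
#' and neuronal (per-cell) population fluorescence. All-zero traces are
#' excluded with a warning.
#'
#' @param traces `units x T` matrix (or a list of equal-length vectors).
#' @return numeric population trace; bounded in [0, 1] for nonnegative
#'   inputs.
#' @export
population_fluorescence <- function(traces) {
  if (is.list(traces)) traces <- do.call(rbind, traces)
  traces <- as.matrix(traces)
  maxima <- apply(traces, 1, max)
  bad <- maxima == 0
  if (any(bad)) {
    warning(sum(bad), " all-zero trace(s) excluded from the population average")
    traces <- traces[!bad, , drop = FALSE]
    maxima <- maxima[!bad]
  }
  if (!nrow(traces)) stop("no usable traces")
  colMeans(traces / maxima)
}

#' Threshold neuronal event times
#'
#' Marks samples of a deconvolved spike-amplitude trace exceeding the
#' mean by more than three standard deviations -- only the largest
#' events.
#'
#' @param spike_trace per-cell deconvolved amplitude trace.
#' @param rate frame rate (for the returned times).
#' @param n_sd threshold in standard deviations above the mean.
#' @return numeric vector of event times in seconds (empty for a
#'   zero-variance trace).
#' @export
detect_neuronal_events <- function(spike_trace, rate = 1, n_sd = 3) {
  s <- sd(spike_trace)
  if (!is.finite(s) || s == 0) return(numeric(0))
  idx <- which(spike_trace > mean(spike_trace) + n_sd * s)
  (idx - 1L) / rate
}

#' Event-triggered average of a trace
#'
#' Snippets in a symmetric window around each event are averaged; the
#' result is the mean and standard error across events. Events whose
#' window extends past the recording are dropped and counted.
#'
#' @param signal numeric trace.
#' @param rate sampling rate in Hz.
#' @param event_times_s event times in seconds.
#' @param window `(pre_s, post_s)` extents of the window in seconds.
#' @return a `triggered_average`: `times_s` (relative to the event),
#'   `mean`, `sem` (zero-width with a warning when only one event),
#'   `n_events`, `n_dropped`.
#' @export
event_triggered_average <- function(signal, rate, event_times_s,
                                    window = c(5, 5)) {
  pre <- round(window[1] * rate)
  post <- round(window[2] * rate)
  centers <- round(event_times_s * rate) + 1L
  ok <- centers - pre >= 1L & centers + post <= length(signal)
  n_dropped <- sum(!ok)
  centers <- centers[ok]
  if (!length(centers)) stop("no events with a full window inside the recording")
  rel <- seq.int(-pre, post)
  snips <- vapply(centers, function(c0) signal[c0 + rel],
                  numeric(length(rel)))
  m <- rowMeans(snips)
  if (length(centers) == 1L) {
    warning("single event: s.e.m. reported as zero-width")
    sem <- rep(0, length(rel))
  } else {
    sem <- apply(snips, 1, sd) / sqrt(length(centers))
  }
  structure(list(times_s = rel / rate, mean = m, sem = sem,
                 n_events = length(centers), n_dropped = n_dropped,
                 window = window),
            class = "triggered_average")
}

#' Normalized cross-correlation of two traces
#'
#' Both traces are z-scored, resampled to a common target rate (linear
#' interpolation), padded with `NA` if unequal in length, and
#' cross-correlated over lags; missing samples are ignored pairwise. The
#' sign convention is that a negative peak lag means `x` leads `y`. An
#' optional state mask (at the target rate) restricts the correlation to
#' moving or stationary samples.
#'
#' @param x,y numeric traces.
#' @param rate_x,rate_y input sampling rates in Hz.
#' @param rate_target common analysis rate in Hz (10 or 30 in practice).
#' @param max_lag_s largest |lag| examined, seconds.
#' @param state_mask optional logical vector at the target rate; `FALSE`
#'   samples are excluded.
#' @param min_pairs lags with fewer valid pairs are reported `NA`.
#' @return a `cross_correlation`: `lags_s`, `r`, `peak_lag_s`, `peak_r`,
#'   `n_pairs`.
#' @export
cross_correlate <- function(x, y, rate_x = 1, rate_y = rate_x,
                            rate_target = 10, max_lag_s = 20,
                            state_mask = NULL, min_pairs = 10) {
  xr <- resample_linear(zscore(x), rate_x, rate_target)
  yr <- resample_linear(zscore(y), rate_y, rate_target)
  n <- max(length(xr), length(yr))
  length(xr) <- n  # NA-pad the shorter trace
  length(yr) <- n
  if (!is.null(state_mask)) {
    m <- rep_len(state_mask, n)
    xr[!m] <- NA
    yr[!m] <- NA
  }
  max_lag <- round(max_lag_s * rate_target)
  lags <- seq.int(-max_lag, max_lag)
  r <- numeric(length(lags))
  npairs <- integer(length(lags))
  for (i in seq_along(lags)) {
    l <- lags[i]
    # r(l) = cor(x(t), y(t - l)): y delayed relative to x peaks at l < 0
    if (l <= 0) {
      xs <- xr[seq_len(n + l)]
      ys <- yr[seq.int(1 - l, n)]
    } else {
      xs <- xr[seq.int(1 + l, n)]
      ys <- yr[seq_len(n - l)]
    }
    ok <- !is.na(xs) & !is.na(ys)
    npairs[i] <- sum(ok)
    r[i] <- if (npairs[i] >= min_pairs) cor(xs[ok], ys[ok]) else NA_real_
  }
  ipk <- which.max(abs(r))
  structure(list(lags_s = lags / rate_target, r = r,
                 peak_lag_s = lags[ipk] / rate_target, peak_r = r[ipk],
                 n_pairs = npairs),
            class = "cross_correlation")
}

#' Mean signal per pupil-diameter decile
#'
#' Samples are partitioned by the recording's own pupil-diameter decile
#' boundaries; the mean of the aligned signal and the sample count per
#' decile are returned. The bins partition all samples.
#'
#' @param pupil a `pupil_trace` or numeric diameter trace.
#' @param signal numeric trace aligned sample-by-sample with the pupil.
#' @return data.frame with `decile`, `mean_signal`, `n`.
#' @export
pupil_decile_binning <- function(pupil, signal) {
  d <- if (inherits(pupil, "pupil_trace")) pupil$diameter else pupil
  if (length(d) != length(signal)) stop("traces must be aligned (equal length)")
  if (length(unique(d)) == 1L) stop("constant pupil: deciles undefined")
  qs <- quantile(d, probs = seq(0, 1, 0.1), names = FALSE, type = 7)
  bin <- findInterval(d, qs, rightmost.closed = TRUE, all.inside = TRUE)
  data.frame(decile = 1:10,
             mean_signal = vapply(1:10, function(b) {
               if (any(bin == b)) mean(signal[bin == b]) else NA_real_
             }, numeric(1)),
             n = vapply(1:10, function(b) sum(bin == b), integer(1)))
}

#' Detect phasic norepinephrine peaks
#'
#' Local maxima with topographic prominence of at least one standard
#' deviation of the trace. Amplitude class is the floor of the prominence
#' in s.d. units (the 1/2/3 s.d. classes); duration is the width at half
#' prominence, with interpolated crossings.
#'
#' @param ne sensor trace.
#' @param rate sampling rate in Hz.
#' @param min_prominence_sd prominence threshold in trace-s.d. units.
#' @return data.frame with `time_s`, `amplitude_sd`, `class`,
#'   `duration_s` (possibly zero rows).
#' @export
detect_ne_peaks <- function(ne, rate = 1, min_prominence_sd = 1) {
  if (length(ne) <= 10 * rate) stop("trace shorter than 10 s")
  s <- sd(ne)
  if (!is.finite(s) || s == 0) {
    return(data.frame(time_s = numeric(0), amplitude_sd = numeric(0),
                      class = integer(0), duration_s = numeric(0)))
  }
  n <- length(ne)
  is_peak <- which(diff(sign(diff(ne))) == -2) + 1L
  rows <- lapply(is_peak, function(p) {
    pk <- ne[p]
    # walk outward until a higher sample (or the edge); the highest
    # minimum passed on either side sets the prominence
    left_min <- pk; i <- p
    while (i > 1L && ne[i - 1L] <= pk) {
      i <- i - 1L
      left_min <- min(left_min, ne[i])
    }
    if (i == 1L) left_min <- min(ne[seq_len(p)])
    right_min <- pk; i <- p
    while (i < n && ne[i + 1L] <= pk) {
      i <- i + 1L
      right_min <- min(right_min, ne[i])
    }
    if (i == n) right_min <- min(ne[p:n])
    prom <- pk - max(left_min, right_min)
    prom_sd <- prom / s
    if (prom_sd < min_prominence_sd) return(NULL)
    half <- pk - prom / 2
    li <- p
    while (li > 1L && ne[li] > half) li <- li - 1L
    t_left <- if (ne[li] > half) li else {
      li + (half - ne[li]) / (ne[li + 1L] - ne[li])
    }
    ri <- p
    while (ri < n && ne[ri] > half) ri <- ri + 1L
    t_right <- if (ne[ri] > half) ri else {
      ri - (half - ne[ri]) / (ne[ri - 1L] - ne[ri])
    }
    data.frame(time_s = (p - 1L) / rate, amplitude_sd = prom_sd,
               class = floor(prom_sd), duration_s = (t_right - t_left) / rate)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(time_s = numeric(0), amplitude_sd = numeric(0),
                      class = integer(0), duration_s = numeric(0))
  }
  out
}

#' Pupil phase at event onsets and offsets
#'
#' Labels each event onset and offset as occurring during dilation
#' (positive pupil derivative) or constriction (negative derivative).
#'
#' @param event_onsets_s,event_offsets_s event times in seconds.
#' @param pupil a [process_pupil()] result.
#' @return data.frame with `onset_phase` and `offset_phase`
#'   (`"dilation"`/`"constriction"`).
#' @export
event_pupil_phase <- function(event_onsets_s, event_offsets_s, pupil) {
  if (!inherits(pupil, "pupil_trace")) stop("`pupil` must be a pupil_trace")
  label <- function(times) {
    idx <- pmin(length(pupil$phase), pmax(1L, round(times * pupil$rate) + 1L))
    ifelse(pupil$phase[idx] > 0, "dilation", "constriction")
  }
  data.frame(onset_phase = label(event_onsets_s),
             offset_phase = label(event_offsets_s))
}

#' Preprocess a fiber-photometry trace
#'
#' Removes bleaching with a linear detrend, z-scores, and denoises with a
#' zero-phase low-pass FIR filter (2 Hz cutoff, 0.5 Hz transition width).
#'
#' @param trace photometry trace.
#' @param rate sampling rate in Hz (> 4 Hz).
#' @param cutoff_hz FIR cutoff.
#' @param transition_hz FIR transition width, sets the filter order.
#' @return filtered trace (mean 0, s.d. 1 before filtering).
#' @export
photometry_preprocess <- function(trace, rate, cutoff_hz = 2,
                                  transition_hz = 0.5) {
  stopifnot_scalar(rate, "rate")
  if (rate <= 4) stop("`rate` must exceed 4 Hz")
  tt <- seq_along(trace)
  fit <- stats::lm.fit(cbind(1, tt), trace)
  x <- trace - fit$fitted.values
  s <- sd(x)
  # z-score; a numerically-exact ramp detrends to zero and stays zero
  # rather than having floating-point residue amplified to unit variance
  if (s > 1e-10 * (diff(range(trace)) + 1)) x <- x / s
  # Hamming-window FIR length from the normalized transition width
  ord <- ceiling(3.3 * rate / transition_hz)
  if (ord %% 2 == 1) ord <- ord + 1
  b <- signal::fir1(ord, cutoff_hz / (rate / 2), type = "low")
  as.numeric(signal::filtfilt(b, x))
}

# Fourth derivative of the logistic in units of the argument u = k(t-t0):
# closed form via powers of s = 1/(1+exp(-u)).
logistic_d4 <- function(u) {
  s <- 1 / (1 + exp(-u))
  s * (1 - s) * (1 - 2 * s) * (1 - 12 * s + 12 * s^2)
}

# Location (in u) of the earliest local extremum of the logistic fourth
# derivative before the midpoint; a shape constant of the logistic,
# computed once by grid search + refinement.
logistic_d4_onset_u <- function() {
  grid <- seq(-12, 0, by = 1e-3)
  v <- logistic_d4(grid)
  dv <- diff(v)
  flips <- which(dv[-1] * dv[-length(dv)] < 0)
  u0 <- grid[flips[1] + 1L]
  maximize <- logistic_d4(u0) > logistic_d4(u0 - 0.05)
  opt <- optimize(logistic_d4, interval = c(u0 - 0.05, u0 + 0.05),
                  maximum = maximize)
  if (maximize) opt$maximum else opt$minimum
}

.onset_cache <- new.env(parent = emptyenv())

#' Startle response onset from a sigmoid fit
#'
#' Fits a four-parameter logistic
#' `A + (B - A) / (1 + exp(-k (t - t0)))` to an evoked snippet
#' (Levenberg-Marquardt) and reports the onset as the earliest local
#' extremum of the fitted curve's analytic fourth derivative preceding
#' the midpoint. That extremum sits at a fixed position in the
#' dimensionless argument `u = k (t - t0)`, so the onset is
#' `t0 + u* / k` -- a fixed offset before the midpoint scaling as `1/k`.
#'
#' @param evoked snippet spanning a rise.
#' @param rate sampling rate in Hz.
#' @return list with `onset_s`, `fit` (named coefficients A, B, k, t0).
#' @export
startle_onset <- function(evoked, rate) {
  stopifnot_scalar(rate, "rate")
  n <- length(evoked)
  tt <- (seq_len(n) - 1) / rate
  lo <- mean(head(evoked, max(3L, n %/% 10)))
  hi <- mean(tail(evoked, max(3L, n %/% 10)))
  if (hi <= lo) stop("snippet does not span a rise; cannot fit a sigmoid")
  half <- (lo + hi) / 2
  t0_start <- tt[which.min(abs(evoked - half))]
  dat <- data.frame(t = tt, y = evoked)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A + (B - A) / (1 + exp(-k * (t - t0))),
                      data = dat,
                      start = list(A = lo, B = hi, k = 4 / (tt[n] - tt[1]) * 4,
                                   t0 = t0_start),
                      lower = c(-Inf, -Inf, 1e-6, tt[1] - diff(range(tt))),
                      upper = c(Inf, Inf, Inf, tt[n] + diff(range(tt))),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("sigmoid fit failed: ", conditionMessage(e))
  )
  cf <- coef(fit)
  if (cf[["B"]] <= cf[["A"]]) stop("fitted sigmoid is non-increasing")
  if (is.null(.onset_cache$u)) .onset_cache$u <- logistic_d4_onset_u()
  onset <- cf[["t0"]] + .onset_cache$u / cf[["k"]]
  list(onset_s = unname(onset), fit = cf)
}
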