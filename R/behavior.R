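#' Wheel speed from an optoswitch voltage trace
#'
#' A break in the optoswitch circuit is detected where the absolute value
#' of the voltage derivative is at least two standard deviations above
#' its mean; for near-flat recordings (s.d. of `|dV|` below 0.1) that
#' rule generates false positives, so a fixed threshold of 0.1 is used
#' instead. Contiguous suprathreshold samples count as one break. Speed
#' is breaks per second times the tab spacing, reported at 1 Hz.
#'
#' @param voltage raw optoswitch voltage.
#' @param rate voltage sampling rate in Hz (>= 100).
#' @param tab_spacing_cm distance between wheel tabs in cm; depends on
#'   wheel circumference and tab count, so no default is assumed.
#' @return a `speed_trace`: `times_s`, `speed` (cm/s at 1 Hz), and the
#'   detection parameters used.
#' @export
compute_wheel_speed <- function(voltage, rate, tab_spacing_cm) {
  stopifnot_scalar(rate, "rate")
  stopifnot_scalar(tab_spacing_cm, "tab_spacing_cm")
  dv <- abs(diff(voltage))
  s <- sd(dv)
  threshold <- if (is.na(s) || s < 0.1) 0.1 else mean(dv) + 2 * s
  supra <- dv >= threshold
  onsets <- which(supra & !c(FALSE, supra[-length(supra)]))
  n_sec <- floor(length(voltage) / rate)
  counts <- tabulate(pmin(n_sec, (onsets - 1L) %/% rate + 1L), nbins = n_sec)
  structure(list(times_s = seq_len(n_sec) - 0.5,
                 speed = counts * tab_spacing_cm,
                 rate = 1,
                 tab_spacing_cm = tab_spacing_cm,
                 threshold_used = threshold),
            class = "speed_trace")
}

as_speed <- function(x, rate = 1) {
  if (inherits(x, "speed_trace")) return(x)
  structure(list(times_s = (seq_along(x) - 0.5) / rate, speed = x,
                 rate = rate, tab_spacing_cm = NA_real_,
                 threshold_used = NA_real_),
            class = "speed_trace")
}

#' Detect movement bouts
#'
#' Movement periods are samples with wheel speed at or above
#' `threshold` (10 cm/s); bouts separated by gaps of at most
#' `merge_gap_s` (2 s) are merged into one event.
#'
#' @param speed a `speed_trace` or numeric speed vector.
#' @param rate sampling rate when `speed` is a bare vector.
#' @param threshold movement threshold in cm/s.
#' @param merge_gap_s maximum gap merged into one bout, seconds.
#' @return data.frame with `onset_s`, `offset_s`, `duration_s`,
#'   `peak_speed` (possibly zero rows).
#' @export
detect_movement_bouts <- function(speed, rate = 1, threshold = 10,
                                  merge_gap_s = 2) {
  sp <- as_speed(speed, rate)
  x <- sp$speed
  r <- sp$rate
  runs <- rle(x >= threshold)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  if (!any(keep)) {
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      duration_s = numeric(0), peak_speed = numeric(0)))
  }
  on <- (starts[keep] - 1L) / r
  off <- ends[keep] / r
  # merge bouts separated by <= merge_gap_s
  m_on <- on[1]; m_off <- off[1]
  out_on <- numeric(0); out_off <- numeric(0)
  for (i in seq_along(on)[-1]) {
    if (on[i] - m_off <= merge_gap_s) {
      m_off <- off[i]
    } else {
      out_on <- c(out_on, m_on); out_off <- c(out_off, m_off)
      m_on <- on[i]; m_off <- off[i]
    }
  }
  out_on <- c(out_on, m_on); out_off <- c(out_off, m_off)
  peak <- vapply(seq_along(out_on), function(i) {
    max(x[seq.int(floor(out_on[i] * r) + 1L, ceiling(out_off[i] * r))])
  }, numeric(1))
  data.frame(onset_s = out_on, offset_s = out_off,
             duration_s = out_off - out_on, peak_speed = peak)
}

#' Stationary-period mask
#'
#' Marks times at least `margin_s` (10 s) away from every movement bout,
#' so movement-related dynamics are excluded from stationary analyses.
#'
#' @param bouts data.frame from [detect_movement_bouts()].
#' @param total_duration_s recording length in seconds.
#' @param rate sampling rate of the returned mask in Hz.
#' @param margin_s exclusion margin around each bout, seconds.
#' @return logical vector (`TRUE` = stationary) with attribute
#'   `times_s`.
#' @export
stationary_mask <- function(bouts, total_duration_s, rate = 1,
                            margin_s = 10) {
  tt <- seq(0, total_duration_s, by = 1 / rate)
  tt <- tt[tt < total_duration_s]
  mask <- rep(TRUE, length(tt))
  for (i in seq_len(nrow(bouts))) {
    mask[tt >= bouts$onset_s[i] - margin_s &
         tt <= bouts$offset_s[i] + margin_s] <- FALSE
  }
  attr(mask, "times_s") <- tt
  mask
}

#' Process a raw pupil-diameter trace
#'
#' Low-pass filters the diameter to 0.5 Hz (zero-phase fourth-order
#' Butterworth), min-max normalizes it to [0, 1] (diameter as fraction of
#' maximum), and computes the derivative normalized to the acquisition
#' rate, with phase as the sign of the derivative (exact zeros inherit
#' the previous nonzero sign).
#'
#' @param raw_diameter positive raw diameter trace.
#' @param rate acquisition rate in Hz (30 Hz pupil video).
#' @param cutoff_hz low-pass cutoff.
#' @return a `pupil_trace`: `diameter` in [0, 1], `derivative` (1/s),
#'   `phase` (+1/-1), `rate`.
#' @export
process_pupil <- function(raw_diameter, rate = 30, cutoff_hz = 0.5) {
  if (length(unique(raw_diameter)) == 1L) {
    stop("constant pupil trace: normalization undefined")
  }
  bf <- signal::butter(4, cutoff_hz / (rate / 2), type = "low")
  x <- signal::filtfilt(bf, raw_diameter)
  x <- (x - min(x)) / (max(x) - min(x))
  d <- diff(x) * rate
  d <- c(d, d[length(d)])
  phase <- sign(d)
  for (i in seq_along(phase)) {
    if (phase[i] == 0) phase[i] <- if (i > 1) phase[i - 1] else 1
  }
  structure(list(diameter = x, derivative = d, phase = phase, rate = rate),
            class = "pupil_trace")
}

#' Build a pupil trace from an already-processed diameter
#'
#' Wraps a normalized diameter trace into the `pupil_trace` structure
#' (derivative and phase computed as in [process_pupil()]) without
#' filtering or re-normalizing.
#'
#' @param diameter diameter trace, fraction of maximum.
#' @param rate sampling rate in Hz.
#' @return a `pupil_trace`.
#' @export
pupil_trace <- function(diameter, rate = 30) {
  if (inherits(diameter, "pupil_trace")) return(diameter)
  d <- diff(diameter) * rate
  d <- c(d, d[length(d)])
  phase <- sign(d)
  for (i in seq_along(phase)) {
    if (phase[i] == 0) phase[i] <- if (i > 1) phase[i - 1] else 1
  }
  structure(list(diameter = diameter, derivative = d, phase = phase,
                 rate = rate),
            class = "pupil_trace")
}

as_pupil <- pupil_trace

#' Detect pupil dilation events
#'
#' Maximal runs of positive pupil derivative are candidate dilations;
#' only changes in diameter greater than `min_delta` (10% of maximum)
#' are retained. Events are labeled `moving` or `stationary` from the
#' mask at their onset.
#'
#' @param pupil a [process_pupil()] result.
#' @param mask optional stationary mask from [stationary_mask()].
#' @param min_delta minimum diameter change, fraction of maximum.
#' @return data.frame with `onset_s`, `offset_s`, `delta`, `context`.
#' @export
detect_dilation_events <- function(pupil, mask = NULL, min_delta = 0.10) {
  if (!inherits(pupil, "pupil_trace")) stop("`pupil` must be a pupil_trace")
  pos <- pupil$derivative > 0
  runs <- rle(pos)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  out <- lapply(which(keep), function(i) {
    i0 <- starts[i]; i1 <- min(ends[i] + 1L, length(pupil$diameter))
    delta <- pupil$diameter[i1] - pupil$diameter[i0]
    if (delta <= min_delta) return(NULL)
    onset_s <- (i0 - 1L) / pupil$rate
    context <- NA_character_
    if (!is.null(mask)) {
      tm <- attr(mask, "times_s")
      j <- findInterval(onset_s, tm)
      context <- if (j >= 1 && mask[j]) "stationary" else "moving"
    }
    data.frame(onset_s = onset_s, offset_s = (i1 - 1L) / pupil$rate,
               delta = delta, context = context)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      delta = numeric(0), context = character(0))
  }
  out
}
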