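#' Identify the arousal principal component
#'
#' PCA on the z-scored neuronal population matrix; each PC time course
#' and the pupil diameter are resampled to an effective 10 Hz, and the PC
#' with the largest absolute Pearson correlation with pupil diameter is
#' the arousal PC. Its sign is fixed so the pupil correlation is
#' positive, and the trace is normalized to its absolute maximum.
#'
#' @param neurons `cells x frames` fluorescence matrix (>= 2 cells).
#' @param frame_rate imaging frame rate in Hz.
#' @param pupil a `pupil_trace` or numeric diameter trace.
#' @param pupil_rate pupil sampling rate when `pupil` is a bare vector.
#' @param rate_target common resampling rate for the correlation, Hz.
#' @return an `arousal_pc`: `component_index`, `weights` (per-cell
#'   loadings), `trace` (frame rate, max-normalized),
#'   `pupil_correlation`, `variance_explained` (all components),
#'   `frame_rate`.
#' @export
identify_arousal_pc <- function(neurons, frame_rate, pupil,
                                pupil_rate = 30, rate_target = 10) {
  neurons <- as.matrix(neurons)
  if (nrow(neurons) < 2L) stop("need at least 2 cells for PC analysis")
  z <- t(apply(neurons, 1, zscore))
  if (any(!is.finite(z))) stop("degenerate (constant) cell trace after z-scoring")
  pd <- if (inherits(pupil, "pupil_trace")) pupil$diameter else pupil
  prate <- if (inherits(pupil, "pupil_trace")) pupil$rate else pupil_rate
  pca <- prcomp(t(z), center = TRUE, scale. = FALSE)
  pupil_rs <- resample_linear(pd, prate, rate_target)
  n_pc <- ncol(pca$x)
  rs <- vapply(seq_len(n_pc), function(j) {
    pc_rs <- resample_linear(pca$x[, j], frame_rate, rate_target)
    m <- min(length(pc_rs), length(pupil_rs))
    cor(pc_rs[seq_len(m)], pupil_rs[seq_len(m)])
  }, numeric(1))
  jbest <- which.max(abs(rs))
  flip <- if (rs[jbest] < 0) -1 else 1
  trace <- flip * pca$x[, jbest]
  trace <- trace / max(abs(trace))
  structure(list(component_index = jbest,
                 weights = flip * pca$rotation[, jbest],
                 trace = trace,
                 pupil_correlation = abs(rs[jbest]),
                 variance_explained = pca$sdev^2 / sum(pca$sdev^2),
                 frame_rate = frame_rate),
            class = "arousal_pc")
}

#' Arousal-PC response per event
#'
#' For each event the PC values in a window around it are normalized to
#' the window median, then averaged over the event period shifted by
#' `offset_frames` (two frames, accounting for the slight lag of the
#' arousal-associated neuronal response). Events whose window leaves the
#' recording are dropped and counted.
#'
#' @param pc an [identify_arousal_pc()] result (or numeric trace with
#'   `frame_rate`).
#' @param onsets_s,offsets_s event periods in seconds.
#' @param offset_frames response lag in frames.
#' @param pad_s window padding on each side of the event, seconds.
#' @param frame_rate required when `pc` is a bare trace.
#' @return numeric vector of per-event responses with attribute
#'   `n_dropped`.
#' @export
pc_event_response <- function(pc, onsets_s, offsets_s, offset_frames = 2,
                              pad_s = 5, frame_rate = NULL) {
  if (inherits(pc, "arousal_pc")) {
    trace <- pc$trace
    rate <- pc$frame_rate
  } else {
    trace <- pc
    rate <- frame_rate
    if (is.null(rate)) stop("`frame_rate` required for a bare trace")
  }
  n <- length(trace)
  pad <- round(pad_s * rate)
  res <- numeric(0)
  dropped <- 0L
  for (i in seq_along(onsets_s)) {
    i0 <- round(onsets_s[i] * rate) + 1L + offset_frames
    i1 <- round(offsets_s[i] * rate) + 1L + offset_frames
    w0 <- i0 - pad; w1 <- i1 + pad
    if (w0 < 1L || w1 > n || i1 < i0) {
      dropped <- dropped + 1L
      next
    }
    win <- trace[w0:w1]
    med <- median(win)
    if (med == 0) {
      dropped <- dropped + 1L
      next
    }
    res <- c(res, mean(trace[i0:i1] / med))
  }
  if (!length(res)) stop("no events with a full window inside the recording")
  attr(res, "n_dropped") <- dropped
  res
}

#' Derivative of the arousal PC
#'
#' First difference scaled by the frame rate, for testing sign changes of
#' arousal-associated neuronal activity around event onsets.
#'
#' @inheritParams pc_event_response
#' @return numeric derivative trace (length `n - 1`).
#' @export
pc_derivative <- function(pc, frame_rate = NULL) {
  if (inherits(pc, "arousal_pc")) {
    diff(pc$trace) * pc$frame_rate
  } else {
    if (is.null(frame_rate)) stop("`frame_rate` required for a bare trace")
    diff(pc) * frame_rate
  }
}
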