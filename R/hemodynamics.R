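#' Pixel movie container
#'
#' A fluorescence pixel movie: `T x H x W` nonnegative array plus frame
#' rate. Pixels are addressed by a flattened row-major index
#' `k = (row - 1) * W + col`, the order used for tie-breaking and for the
#' pixel-by-time matrix view.
#'
#' @param data `T x H x W` numeric array, or a `pixels x T` matrix
#'   together with `dim_spatial`.
#' @param frame_rate frames per second.
#' @param dim_spatial `(H, W)` when `data` is a pixel matrix.
#' @return a `pixel_movie` object.
#' @export
pixel_movie <- function(data, frame_rate, dim_spatial = NULL) {
  stopifnot_scalar(frame_rate, "frame_rate")
  if (is.matrix(data)) {
    if (is.null(dim_spatial)) stop("`dim_spatial` required for matrix input")
    h <- dim_spatial[1]; w <- dim_spatial[2]
    if (nrow(data) != h * w) stop("pixel count does not match dim_spatial")
    arr <- array(0, c(ncol(data), h, w))
    for (k in seq_len(nrow(data))) {
      r <- (k - 1L) %/% w + 1L
      c_ <- (k - 1L) %% w + 1L
      arr[, r, c_] <- data[k, ]
    }
    data <- arr
  }
  if (length(dim(data)) != 3L) stop("`data` must be a T x H x W array")
  if (any(!is.finite(data))) stop("movie contains non-finite values")
  structure(list(data = data, frame_rate = frame_rate), class = "pixel_movie")
}

#' @export
dim.pixel_movie <- function(x) dim(x$data)

#' Pixel-by-time matrix view of a movie
#'
#' @param movie a [pixel_movie()].
#' @return `(H*W) x T` matrix; row `k` is the flattened row-major pixel
#'   `k`.
#' @export
movie_pixels <- function(movie) {
  d <- dim(movie$data)
  t_ <- d[1]; h <- d[2]; w <- d[3]
  out <- matrix(0, h * w, t_)
  for (r in seq_len(h)) {
    for (c_ in seq_len(w)) {
      out[(r - 1L) * w + c_, ] <- movie$data[, r, c_]
    }
  }
  out
}

#' Centered moving-average detrend
#'
#' Subtracts a centered 100-frame moving average from a trace, removing
#' slow changes (including slow true sensor signal) before the
#' attenuation fit. The window shrinks symmetrically at the edges, so no
#' phase shift is introduced.
#'
#' @param trace numeric vector.
#' @param window nominal window width in frames.
#' @return detrended trace of the same length.
#' @export
detrend_moving_average <- function(trace, window = 100) {
  if (length(trace) <= window) stop("trace must be longer than the detrend window")
  trace - moving_average(trace, window)
}

#' Select the vascular reference region
#'
#' Finds a spatially connected region of `region_size` pixels minimizing
#' mean-projection intensity -- the region least likely to carry true
#' sensor signal -- by greedy dimmest-neighbor growth from every seed
#' pixel (4-connectivity), keeping the candidate with the lowest mean.
#' Ties are broken by the smallest flattened row-major seed index. The
#' reference curve is the spatial mean of the region's traces, detrended
#' with [detrend_moving_average()].
#'
#' @param movie a [pixel_movie()].
#' @param region_size region size in pixels (>= 4).
#' @param window detrend window in frames.
#' @return a `vascular_reference`: `pixel_idx` (flattened indices),
#'   `mask` (H x W logical), `ref_curve` (zero-mean), `iteration = 0`.
#' @export
select_vascular_reference <- function(movie, region_size = 9, window = 100) {
  if (region_size < 4) stop("`region_size` must be at least 4 pixels")
  d <- dim(movie$data)
  h <- d[2]; w <- d[3]
  if (region_size > h * w) stop("no connected region of the requested size exists")
  proj <- apply(movie$data, c(2, 3), mean)  # H x W mean projection
  flat <- as.numeric(t(proj))               # row-major
  n <- h * w
  neighbors <- function(k) {
    r <- (k - 1L) %/% w + 1L
    c_ <- (k - 1L) %% w + 1L
    out <- integer(0)
    if (r > 1L) out <- c(out, k - w)
    if (r < h) out <- c(out, k + w)
    if (c_ > 1L) out <- c(out, k - 1L)
    if (c_ < w) out <- c(out, k + 1L)
    out
  }
  best_mean <- Inf
  best_set <- NULL
  for (seed in seq_len(n)) {
    set <- seed
    frontier <- neighbors(seed)
    while (length(set) < region_size && length(frontier) > 0L) {
      vals <- flat[frontier]
      pick <- frontier[order(vals, frontier)[1L]]
      set <- c(set, pick)
      frontier <- unique(c(setdiff(frontier, pick),
                           setdiff(neighbors(pick), set)))
    }
    if (length(set) < region_size) next
    m <- mean(flat[set])
    if (m < best_mean - 1e-12) {
      best_mean <- m
      best_set <- sort(set)
    }
  }
  if (is.null(best_set)) stop("no connected region of the requested size exists")
  px <- movie_pixels(movie)
  ref_raw <- colMeans(px[best_set, , drop = FALSE])
  ref <- detrend_moving_average(ref_raw, window)
  mask <- matrix(FALSE, h, w)
  for (k in best_set) mask[(k - 1L) %/% w + 1L, (k - 1L) %% w + 1L] <- TRUE
  structure(list(pixel_idx = best_set, mask = mask, ref_curve = ref,
                 iteration = 0L, window = window),
            class = "vascular_reference")
}

#' Fit the per-pixel attenuation model
#'
#' Ordinary least squares of the logarithm of each (detrended) pixel
#' curve against the vascular reference curve. A detrended curve whose
#' minimum is not strictly positive is first offset by
#' `|min| + eps * (max - min)` so the logarithm is defined; the offsets
#' are recorded in the fit for reproducibility. The fitted slope `a` is
#' the per-pixel hemodynamic weight; the attenuation exponent time course
#' is `a * ref_curve(t) + b`.
#'
#' @param movie_detrended `pixels x T` matrix of detrended traces (or a
#'   [pixel_movie()], detrended per pixel internally).
#' @param ref a `vascular_reference` (or zero-mean numeric reference
#'   curve).
#' @param offsets optional per-pixel positivity offsets added before the
#'   logarithm. The natural choice is each pixel's raw-curve mean
#'   (restoring the brightness the detrend removed), which makes the
#'   log-slope directly proportional to the attenuation gain;
#'   [correct_hemodynamics()] passes that. When `NULL`, traces already
#'   strictly positive are used as-is and others are offset by
#'   `|min| + eps * range`.
#' @param eps relative positivity margin for the fallback offset.
#' @param window detrend window when `movie_detrended` is a movie.
#' @return a `hemo_fit` with `a`, `b`, `fit_r2`, `offsets`, `ref_curve`.
#' @export
fit_attenuation <- function(movie_detrended, ref, offsets = NULL,
                            eps = 0.05, window = 100) {
  px <- if (inherits(movie_detrended, "pixel_movie")) {
    t(apply(movie_pixels(movie_detrended), 1, detrend_moving_average, window = window))
  } else {
    as.matrix(movie_detrended)
  }
  ref_curve <- if (inherits(ref, "vascular_reference")) ref$ref_curve else ref
  if (length(ref_curve) != ncol(px)) stop("reference length does not match traces")
  if (sd(ref_curve) == 0) stop("degenerate reference curve (zero variance)")
  if (is.null(offsets)) {
    mins <- apply(px, 1, min)
    rngs <- apply(px, 1, max) - mins
    offsets <- ifelse(mins <= 0, abs(mins) + eps * pmax(rngs, .Machine$double.eps), 0)
  } else {
    offsets <- rep_len(offsets, nrow(px))
    if (any(px + offsets <= 0)) stop("supplied offsets do not make all traces positive")
  }
  logs <- log(px + offsets)
  xc <- ref_curve - mean(ref_curve)
  sxx <- sum(xc^2)
  ym <- rowMeans(logs)
  yc <- logs - ym
  a <- as.numeric(yc %*% xc) / sxx
  b <- unname(ym - a * mean(ref_curve))
  ss_res <- rowSums((yc - outer(a, xc))^2)
  ss_tot <- rowSums(yc^2)
  r2 <- unname(ifelse(ss_tot > 0, 1 - ss_res / ss_tot, 0))
  offsets <- unname(offsets)
  structure(list(a = a, b = b, fit_r2 = r2, offsets = offsets,
                 ref_curve = ref_curve, eps = eps),
            class = "hemo_fit")
}

#' Build a fit object from known attenuation parameters
#'
#' Packs externally known per-pixel gains/offsets and an attenuation time
#' course into a `hemo_fit`, e.g. to invert a movie whose contamination
#' parameters are known exactly.
#'
#' @param a,b per-pixel gain and offset.
#' @param ref_curve shared attenuation time course `h(t)`.
#' @return a `hemo_fit`.
#' @export
hemo_fit <- function(a, b, ref_curve) {
  if (length(b) == 1L) b <- rep(b, length(a))
  if (length(a) != length(b)) stop("`a` and `b` lengths differ")
  structure(list(a = a, b = b, fit_r2 = rep(NA_real_, length(a)),
                 offsets = rep(0, length(a)), ref_curve = ref_curve,
                 eps = NA_real_),
            class = "hemo_fit")
}

#' Iteratively refine the vascular reference
#'
#' To tolerate an initially contaminated reference, the reference curve
#' is recomputed as the `a`-weighted average of all pixels' original
#' curves (the fitted attenuation gain of each pixel is its weight,
#' negative gains contribute zero), detrended, and the attenuation refit;
#' this repeats `n_iter` times or until successive references correlate
#' above `tol`. Each pixel's curve enters the average in relative units
#' (divided by its own mean brightness) so that dim, strongly attenuated
#' vascular pixels are not drowned out by bright reporter pixels, and
#' the update is restricted to the most attenuated quartile of pixels
#' (`weight_quantile`): pixels dominated by true sensor signal would
#' otherwise leak that shared signal into the reference, which the
#' correction would then remove from every pixel.
#'
#' @param movie a [pixel_movie()].
#' @param fit a `hemo_fit` from the previous round.
#' @param n_iter maximum refinement rounds.
#' @param window detrend window in frames.
#' @param tol correlation between successive references at which
#'   refinement is declared converged.
#' @param weight_quantile pixels below this quantile of `a` get zero
#'   weight in the reference update.
#' @return list with `ref` (a `vascular_reference` carrying the final
#'   curve), `fit` (the refit on the final reference), and `n_done`.
#' @export
refine_reference <- function(movie, fit, n_iter = 3, window = 100,
                             tol = 0.999, weight_quantile = 0.75) {
  px <- movie_pixels(movie)
  detr <- t(apply(px, 1, detrend_moving_average, window = window))
  means <- rowMeans(px)
  rel <- px / ifelse(means > 0, means, 1)
  offsets <- if (all(means > 0)) means else NULL
  ref_curve <- fit$ref_curve
  n_done <- 0L
  for (i in seq_len(n_iter)) {
    w_ <- pmax(fit$a, 0)
    if (weight_quantile > 0 && length(w_) > 4L) {
      cut <- quantile(fit$a, weight_quantile, names = FALSE)
      keep_top <- fit$a >= cut
      if (any(keep_top)) w_[!keep_top] <- 0
    }
    if (sum(w_) == 0) stop("all refinement weights are zero")
    new_raw <- as.numeric(crossprod(rel, w_)) / sum(w_)
    new_ref <- detrend_moving_average(new_raw, window)
    n_done <- i
    converged <- sd(ref_curve) > 0 && cor(new_ref, ref_curve) > tol
    ref_curve <- new_ref
    fit <- fit_attenuation(detr, ref_curve, offsets = offsets, eps = fit$eps)
    if (converged) break
  }
  ref <- structure(list(pixel_idx = integer(0), mask = NULL,
                        ref_curve = ref_curve, iteration = n_done,
                        window = window),
                   class = "vascular_reference")
  list(ref = ref, fit = fit, n_done = n_done)
}

#' Remove the fitted attenuation from a movie
#'
#' Divides each raw pixel curve by the exponential of its fitted
#' attenuation time course, `F(t) ~ Y(t) / exp(a * ref(t) + b)`. Pixels
#' fitted with `a = 0, b = 0` pass through unchanged.
#'
#' @param movie a [pixel_movie()].
#' @param fit a `hemo_fit` covering all pixels.
#' @return a `corrected_signal` with `corrected_pixels`
#'   (`pixels x T`), and slots for the reporter mask / final trace filled
#'   by [select_reporter_pixels()] and [corrected_grabne_signal()].
#' @export
apply_correction <- function(movie, fit) {
  px <- movie_pixels(movie)
  if (length(fit$a) != nrow(px)) stop("fit does not cover all pixels")
  h_hat <- outer(fit$a, fit$ref_curve) + fit$b
  if (any(!is.finite(h_hat))) stop("non-finite fitted attenuation")
  corrected <- px / exp(h_hat)
  structure(list(corrected_pixels = corrected, fit = fit,
                 frame_rate = movie$frame_rate,
                 reporter_mask = NULL, final_trace = NULL),
            class = "corrected_signal")
}

#' Select reporter pixels by attenuation rank
#'
#' Keeps the least hemodynamically affected pixels: ranked ascending by
#' fitted `a` (ties broken by pixel index), ranks in the half-open
#' percentile interval (1%, 25%] are retained -- the bottom 1%, which
#' often contains artifacts, is excluded. With `n` pixels the mask size
#' is exactly `floor(0.25 n) - floor(0.01 n)`.
#'
#' @param fit a `hemo_fit`.
#' @param pct_low,pct_high percentile bounds (exclusive low, inclusive
#'   high).
#' @return integer vector of retained pixel indices.
#' @export
select_reporter_pixels <- function(fit, pct_low = 1, pct_high = 25) {
  n <- length(fit$a)
  if (n < 100) {
    stop("fewer than 100 pixels; percentile ranks are not meaningful ",
         "(relax pct_low/pct_high for small movies)")
  }
  ord <- order(fit$a, seq_len(n))
  lo <- floor(pct_low / 100 * n)
  hi <- floor(pct_high / 100 * n)
  if (hi <= lo) stop("empty reporter percentile band")
  sort(ord[(lo + 1L):hi])
}

#' Final corrected sensor signal
#'
#' Frame-wise mean of the corrected traces over the reporter pixels.
#'
#' @param corrected a `corrected_signal`.
#' @param reporter_idx pixel indices from [select_reporter_pixels()].
#' @return the `corrected_signal` with `reporter_mask` and `final_trace`
#'   filled in.
#' @export
corrected_grabne_signal <- function(corrected, reporter_idx) {
  if (length(reporter_idx) == 0L) stop("empty reporter mask")
  corrected$reporter_mask <- reporter_idx
  corrected$final_trace <-
    colMeans(corrected$corrected_pixels[reporter_idx, , drop = FALSE])
  corrected
}

#' Full hemodynamic-correction pipeline
#'
#' Reference selection, attenuation fit, iterative reference refinement,
#' correction, reporter-pixel selection, and averaging into the final
#' corrected sensor trace.
#'
#' @param movie a [pixel_movie()].
#' @param region_size vascular region size in pixels.
#' @param window detrend window in frames.
#' @param n_iter refinement iterations.
#' @param pct_low,pct_high reporter percentile bounds.
#' @param eps positivity margin for the log offset.
#' @return a `corrected_signal` with `final_trace`, plus `reference` and
#'   a `report` list (offsets, iterations, percentiles).
#' @export
correct_hemodynamics <- function(movie, region_size = 9, window = 100,
                                 n_iter = 3, pct_low = 1, pct_high = 25,
                                 eps = 0.05) {
  ref0 <- select_vascular_reference(movie, region_size, window)
  px <- movie_pixels(movie)
  detr <- t(apply(px, 1, detrend_moving_average, window = window))
  means <- rowMeans(px)
  offsets <- if (all(means > 0)) means else NULL
  fit <- fit_attenuation(detr, ref0, offsets = offsets, eps = eps)
  refined <- refine_reference(movie, fit, n_iter = n_iter, window = window)
  corrected <- apply_correction(movie, refined$fit)
  reporters <- select_reporter_pixels(refined$fit, pct_low, pct_high)
  corrected <- corrected_grabne_signal(corrected, reporters)
  corrected$reference <- refined$ref
  corrected$initial_reference <- ref0
  corrected$report <- list(region_size = region_size, window = window,
                           n_iter_requested = n_iter,
                           n_iter_done = refined$n_done,
                           pct_low = pct_low, pct_high = pct_high,
                           eps = eps)
  corrected
}

#' Per-pixel correlation with a regressor
#'
#' Pearson correlation of every pixel trace with a behavioral regressor
#' (e.g. pupil diameter resampled to the frame rate) -- a validation map:
#' the corrected signal should track high-correlation pixels and not the
#' vascular region. Zero-variance pixels are reported as `NA`, not zero.
#'
#' @param pixels a [pixel_movie()], `corrected_signal`, or `pixels x T`
#'   matrix.
#' @param regressor numeric trace already at the frame rate.
#' @return numeric vector of per-pixel correlations.
#' @export
pixelwise_regressor_correlation <- function(pixels, regressor) {
  px <- if (inherits(pixels, "pixel_movie")) {
    movie_pixels(pixels)
  } else if (inherits(pixels, "corrected_signal")) {
    pixels$corrected_pixels
  } else {
    as.matrix(pixels)
  }
  if (ncol(px) != length(regressor)) stop("regressor length must match frame count")
  unname(apply(px, 1, function(tr) {
    if (sd(tr) == 0 || sd(regressor) == 0) NA_real_ else cor(tr, regressor)
  }))
}
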