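#' Simulation configuration
#'
#' Parameters of a synthetic multimodal arousal session. Defaults emulate
#' the recording conditions the analysis pipeline targets: 30 Hz pupil
#' video, ~2 Hz two-photon imaging, 1 kHz LFP, ~20 Hz photometry;
#' movement bouts driving pupil dilations; tonic 1/f norepinephrine with
#' phasic peaks in 1/2/3 s.d. amplitude classes whose durations grow with
#' amplitude; astrocyte events lagging NE rises by `astro_lag_s`; a
#' neuronal population carrying a planted arousal component; LFP
#' alternating between low-frequency-dominated (2-7 Hz) and
#' high-frequency-dominated (70-100 Hz) states with a stated fraction of
#' astrocyte events at HF-to-LF transitions; and an optional pixel movie
#' with multiplicative hemodynamic contamination.
#'
#' @param duration_s session length in seconds.
#' @param rates named list of per-stream sampling rates in Hz.
#' @param movement_bout_rate bouts per minute.
#' @param pupil_noise_sd additive pupil noise, normalized units.
#' @param ne_tonic_exponent 1/f^beta slope of tonic NE.
#' @param ne_phasic_rate phasic NE peaks per minute (total, including
#'   dilation-locked peaks).
#' @param astro_lag_s astrocyte event onset lag after an NE rise, seconds.
#' @param hemo list: `n_pixels`, `gain_range` (per-pixel attenuation gain
#'   a), `offset_range` (per-pixel offset b), `noise_sd` (additive sensor
#'   noise).
#' @param lfp_state list: `lf_band`, `hf_band` (Hz), `transition_coupling`
#'   (fraction of astrocyte events with an HF-to-LF transition planted at
#'   their onset), `mean_epoch_s`.
#' @param n_neurons neuronal population size.
#' @param neuron_noise_sd per-cell noise s.d. relative to the unit-variance
#'   arousal signal.
#' @param seed integer RNG seed; identical seed gives bit-identical
#'   sessions.
#' @return a `sim_config` list.
#' @export
sim_config <- function(duration_s = 600,
                       rates = list(pupil = 30, imaging = 2, lfp = 1000,
                                    photometry = 20, speed = 10),
                       movement_bout_rate = 2,
                       pupil_noise_sd = 0.02,
                       ne_tonic_exponent = 0.95,
                       ne_phasic_rate = 4,
                       astro_lag_s = 2,
                       hemo = list(n_pixels = 100,
                                   gain_range = c(0.1, 0.8),
                                   offset_range = c(-0.1, 0.1),
                                   noise_sd = 0.6),
                       lfp_state = list(lf_band = c(2, 7),
                                        hf_band = c(70, 100),
                                        transition_coupling = 0.8,
                                        mean_epoch_s = 20),
                       n_neurons = 30,
                       neuron_noise_sd = 0.5,
                       seed = 1L) {
  stopifnot_scalar(duration_s, "duration_s")
  for (r in names(rates)) stopifnot_scalar(rates[[r]], paste0("rates$", r))
  if (movement_bout_rate < 0) stop("`movement_bout_rate` must be >= 0")
  if (any(hemo$gain_range < 0)) stop("`gain_range` must be nonnegative")
  lf <- lfp_state$lf_band; hf <- lfp_state$hf_band
  if (lf[1] >= lf[2] || hf[1] >= hf[2] || lf[2] > hf[1]) {
    stop("LFP bands must be increasing and non-overlapping (LF below HF)")
  }
  if (lfp_state$transition_coupling < 0 || lfp_state$transition_coupling > 1) {
    stop("`transition_coupling` must lie in [0, 1]")
  }
  structure(list(duration_s = duration_s, rates = rates,
                 movement_bout_rate = movement_bout_rate,
                 pupil_noise_sd = pupil_noise_sd,
                 ne_tonic_exponent = ne_tonic_exponent,
                 ne_phasic_rate = ne_phasic_rate,
                 astro_lag_s = astro_lag_s, hemo = hemo,
                 lfp_state = lfp_state, n_neurons = n_neurons,
                 neuron_noise_sd = neuron_noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a contaminated sensor pixel movie
#'
#' Instantiates the multiplicative attenuation model on known true
#' fluorescence: each pixel k emits
#' `Y_k(t) = F_k(t) * exp(a_k * h(t) + b_k) + N(t)` with per-pixel gain
#' and offset drawn from the configured ranges. Pixels listed in
#' `vascular_idx` are given gains at the top of the range (the generator
#' side of a dim vascular region).
#'
#' @param F_true `pixels x T` matrix of strictly positive true
#'   fluorescence.
#' @param h_true shared attenuation time course, length `T`.
#' @param config a [sim_config()] (its `hemo` block is used), or a list
#'   with `gain_range`, `offset_range`, `noise_sd`.
#' @param frame_rate frames per second of the output movie.
#' @param vascular_idx pixel indices to treat as vascular (high gain).
#' @return list: `movie` (a [pixel_movie()]), `a`, `b`, `noise`
#'   (`pixels x T`).
#' @export
simulate_contaminated_movie <- function(F_true, h_true, config,
                                        frame_rate = 2,
                                        vascular_idx = integer(0)) {
  F_true <- as.matrix(F_true)
  if (any(F_true <= 0)) {
    stop("`F_true` must be strictly positive (multiplicative model)")
  }
  if (ncol(F_true) != length(h_true)) stop("`h_true` length must match frames")
  hemo <- if (inherits(config, "sim_config")) config$hemo else config
  n <- nrow(F_true)
  a <- runif(n, hemo$gain_range[1], hemo$gain_range[2])
  if (length(vascular_idx)) {
    a[vascular_idx] <- max(hemo$gain_range) * runif(length(vascular_idx), 0.9, 1)
  }
  b <- runif(n, hemo$offset_range[1], hemo$offset_range[2])
  noise <- matrix(rnorm(n * ncol(F_true), sd = hemo$noise_sd), n)
  y <- F_true * exp(outer(a, h_true) + b) + noise
  # prefer an exact H x W factorization close to square; pad only if n is
  # awkward (e.g. prime), duplicating the last pixel
  h_dim <- floor(sqrt(n))
  while (h_dim > 1L && n %% h_dim != 0L) h_dim <- h_dim - 1L
  if (h_dim >= max(2L, floor(sqrt(n)) - 5L)) {
    w <- n %/% h_dim
  } else {
    w <- ceiling(sqrt(n))
    h_dim <- ceiling(n / w)
    pad <- matrix(rep(y[n, ], h_dim * w - n), ncol = ncol(y), byrow = TRUE)
    y <- rbind(y, pad)
  }
  list(movie = pixel_movie(y, frame_rate, dim_spatial = c(h_dim, w)),
       a = a, b = b, noise = noise)
}

#' Simulate a full multimodal session with ground truth
#'
#' Generates time-aligned pupil, speed, NE, astrocyte-event,
#' neuronal-population and bilateral LFP streams with the planted causal
#' structure described in [sim_config()], plus (optionally) a
#' hemodynamically contaminated pixel movie and a photometry trace with
#' startle responses. All planted parameters are returned as ground truth
#' for recovery testing.
#'
#' @param config a [sim_config()].
#' @param make_movie generate the contaminated pixel movie.
#' @param make_photometry generate the photometry stream.
#' @return list with `bundle` (a `session_bundle`) and `truth` (a
#'   `ground_truth` list of planted parameters).
#' @export
simulate_session <- function(config, make_movie = FALSE,
                             make_photometry = FALSE) {
  if (!inherits(config, "sim_config")) stop("`config` must be a sim_config")
  set.seed(config$seed)
  dur <- config$duration_s
  r <- config$rates

  ## movement bouts and wheel speed -------------------------------------
  if (config$movement_bout_rate > 0 && dur < 40) {
    stop("duration too short to place any movement bout")
  }
  bout_on <- numeric(0)
  if (config$movement_bout_rate > 0) {
    cand <- poisson_times(config$movement_bout_rate / 60, dur, margin_s = 15)
    for (t0 in cand) {  # enforce separation so bouts stay distinct
      if (!length(bout_on) || t0 - tail(bout_on, 1) > 15) {
        bout_on <- c(bout_on, t0)
      }
    }
  }
  bout_dur <- runif(length(bout_on), 2, 6)
  n_speed <- round(dur * r$speed)
  t_speed <- (seq_len(n_speed) - 1) / r$speed
  speed <- numeric(n_speed)
  bout_peak <- runif(length(bout_on), 14, 25)
  for (i in seq_along(bout_on)) {
    idx <- t_speed >= bout_on[i] & t_speed < bout_on[i] + bout_dur[i]
    ramp <- pmin(1, pmin(t_speed[idx] - bout_on[i],
                         bout_on[i] + bout_dur[i] - t_speed[idx]) / 0.5)
    speed[idx] <- pmax(speed[idx], 10 + (bout_peak[i] - 10) * ramp)
  }

  ## pupil ---------------------------------------------------------------
  n_pupil <- round(dur * r$pupil)
  t_pupil <- (seq_len(n_pupil) - 1) / r$pupil
  slow <- powerlaw_noise(n_pupil, 2) * 0.05
  stat_dil <- poisson_times(1.5 / 60, dur, margin_s = 20)
  # keep stationary dilations clear of movement bouts
  if (length(bout_on)) {
    keep <- vapply(stat_dil, function(t0) {
      all(t0 < bout_on - 15 | t0 > bout_on + bout_dur + 15)
    }, logical(1))
    stat_dil <- stat_dil[keep]
  }
  dil_on <- c(bout_on, stat_dil)
  dil_amp <- c(runif(length(bout_on), 0.25, 0.4),
               runif(length(stat_dil), 0.15, 0.3))
  ord <- order(dil_on)
  dil_on <- dil_on[ord]; dil_amp <- dil_amp[ord]
  pupil_kernel <- transient_kernel(1.5, 6, r$pupil)
  pupil_raw <- 0.35 + slow +
    add_transients(n_pupil, r$pupil, dil_on, dil_amp, pupil_kernel) +
    rnorm(n_pupil, sd = config$pupil_noise_sd)
  pupil <- (pupil_raw - min(pupil_raw)) / (max(pupil_raw) - min(pupil_raw))

  ## norepinephrine ------------------------------------------------------
  n_img <- round(dur * r$imaging)
  t_img <- (seq_len(n_img) - 1) / r$imaging
  tonic <- powerlaw_noise(n_img, config$ne_tonic_exponent)
  extra_rate <- max(0, config$ne_phasic_rate / 60 - length(dil_on) / dur)
  ne_on <- sort(c(dil_on, poisson_times(extra_rate, dur, margin_s = 10)))
  ne_class <- sample(1:3, length(ne_on), replace = TRUE,
                     prob = c(0.5, 0.3, 0.2))
  ne <- tonic
  for (cls in 1:3) {
    sel <- ne_class == cls
    if (!any(sel)) next
    kern <- transient_kernel(0.8, 2 + 1.5 * cls, r$imaging)
    ne <- ne + add_transients(n_img, r$imaging, ne_on[sel],
                              rep(cls, sum(sel)), kern)
  }

  ## astrocyte events ----------------------------------------------------
  coupled <- runif(length(ne_on)) < 0.9
  astro_on_s <- ne_on[coupled] + config$astro_lag_s
  astro_on_s <- astro_on_s[astro_on_s < dur - 15]
  n_ev <- length(astro_on_s)
  ev_dur_fr <- sample(3:8, n_ev, replace = TRUE)
  ev_area <- exp(rnorm(n_ev, log(40), 0.5))
  ev_area <- pmax(ev_area, 10.5)
  ev_amp <- 0.5 + ev_area / 80
  events <- data.frame(
    onset_frame = round(astro_on_s * r$imaging) + 1L,
    offset_frame = round(astro_on_s * r$imaging) + 1L + ev_dur_fr,
    area_um2 = ev_area,
    significance = runif(n_ev, 0, 0.04),
    amplitude = ev_amp
  )
  # decoy events violating each inclusion rule
  n_decoy <- max(2L, round(n_ev / 5))
  decoy_on <- runif(n_decoy, 5, dur - 15)
  decoy <- data.frame(
    onset_frame = round(decoy_on * r$imaging) + 1L,
    offset_frame = round(decoy_on * r$imaging) + 1L +
      ifelse(seq_len(n_decoy) %% 3 == 0, 0L, 4L),
    area_um2 = ifelse(seq_len(n_decoy) %% 3 == 1, 5, 40),
    significance = ifelse(seq_len(n_decoy) %% 3 == 2, 0.5, 0.01),
    amplitude = rep(0.3, n_decoy)
  )
  astro_events <- rbind(events, decoy)
  astro_events <- astro_events[order(astro_events$onset_frame), ]
  rownames(astro_events) <- NULL
  astro_kernel <- transient_kernel(1, 3.5, r$imaging)
  astro_population <- add_transients(n_img, r$imaging, astro_on_s,
                                     ev_amp, astro_kernel) +
    rnorm(n_img, sd = 0.05)

  ## neuronal population -------------------------------------------------
  arousal_weights <- runif(config$n_neurons, 0.2, 1)
  pupil_img <- resample_linear(pupil, r$pupil, r$imaging)[seq_len(n_img)]
  pupil_z <- zscore(pupil_img)
  neuron_matrix <- outer(arousal_weights, pupil_z) +
    matrix(rnorm(config$n_neurons * n_img, sd = config$neuron_noise_sd),
           config$n_neurons)

  ## LFP with planted state structure ------------------------------------
  st <- config$lfp_state
  anchors <- numeric(0)
  if (n_ev > 0 && st$transition_coupling > 0) {
    n_anchor <- round(st$transition_coupling * n_ev)
    cand <- sort(astro_on_s[seq_len(n_ev) %in%
                              sample(n_ev, n_anchor)])
    for (t0 in cand) {  # anchors need room for an HF epoch before them
      if ((!length(anchors) || t0 - tail(anchors, 1) > 12) &&
          t0 > 10 && t0 < dur - 10) {
        anchors <- c(anchors, t0)
      }
    }
  }
  lfp_ipsi <- simulate_state_lfp(dur, r$lfp, st, anchors)
  lfp_contra <- simulate_state_lfp(dur, r$lfp, st, anchors)

  ## optional movie ------------------------------------------------------
  movie <- NULL; movie_truth <- NULL
  if (make_movie) {
    np <- config$hemo$n_pixels
    w <- ceiling(sqrt(np))
    n_vasc <- max(4L, round(0.1 * np))
    vascular_idx <- seq_len(n_vasc)   # contiguous row-major block
    baseline <- runif(np, 80, 120)
    coupling <- runif(np, 0.5, 1)
    baseline[vascular_idx] <- runif(n_vasc, 12, 18)
    coupling[vascular_idx] <- 0.02
    ne_z <- zscore(ne)
    mod <- 1 + 0.08 * outer(coupling, ne_z)
    mod[mod < 0.2] <- 0.2
    F_true <- baseline * mod
    bp <- signal::butter(2, c(0.05, 0.5) / (r$imaging / 2), type = "pass")
    h_base <- signal::filtfilt(bp, rnorm(n_img))
    h_base <- h_base / sd(h_base) * 0.3
    dip_kernel <- transient_kernel(1, 4, r$imaging)
    h_true <- h_base - add_transients(n_img, r$imaging, bout_on,
                                      rep(0.25, length(bout_on)), dip_kernel)
    h_true <- h_true - mean(h_true)
    sim <- simulate_contaminated_movie(F_true, h_true, config,
                                       frame_rate = r$imaging,
                                       vascular_idx = vascular_idx)
    movie <- sim$movie
    movie_truth <- list(hemo_a_true = sim$a, hemo_b_true = sim$b,
                        h_true = h_true, F_true = F_true,
                        noise_trace = sim$noise,
                        vascular_idx = vascular_idx)
  }

  ## optional photometry --------------------------------------------------
  photometry <- NULL; startle_times <- NULL
  if (make_photometry) {
    n_ph <- round(dur * r$photometry)
    t_ph <- (seq_len(n_ph) - 1) / r$photometry
    startle_times <- seq(60, dur - 30, by = 120)
    ph <- 5 - 0.001 * t_ph + 0.1 * powerlaw_noise(n_ph, 1)
    for (t0 in startle_times) {
      ph <- ph + 2 / (1 + exp(-2 * (t_ph - t0 - 1)))
      ph <- ph - 2 / (1 + exp(-0.3 * (t_ph - t0 - 12)))
    }
    photometry <- ph + rnorm(n_ph, sd = 0.05)
  }

  bundle <- structure(list(
    pupil = pupil, speed = speed, ne = ne,
    astro_events = astro_events, astro_population = astro_population,
    neuron_matrix = neuron_matrix,
    lfp_ipsi = lfp_ipsi, lfp_contra = lfp_contra,
    movie = movie, photometry = photometry,
    rates = list(pupil = r$pupil, speed = r$speed, imaging = r$imaging,
                 lfp = r$lfp, photometry = r$photometry),
    duration_s = dur
  ), class = "session_bundle")

  truth <- structure(c(list(
    movement_bouts = data.frame(onset_s = bout_on,
                                duration_s = bout_dur,
                                peak_speed = bout_peak),
    dilation_onsets_s = dil_on,
    stationary_dilation_onsets_s = stat_dil,
    dilation_amplitudes = dil_amp,
    ne_peak_onsets_s = ne_on, ne_peak_classes = ne_class,
    event_onsets_s = astro_on_s,
    astro_lag_s = config$astro_lag_s,
    state_transition_s = anchors,
    arousal_weights = arousal_weights,
    startle_times_s = startle_times
  ), movie_truth), class = "ground_truth")

  list(bundle = bundle, truth = truth)
}

# LFP as state-gated band-limited carriers plus a pink background.
# `anchors` are the HF-to-LF transition times; one LF-to-HF transition is
# inserted at a random time between consecutive anchors so the state
# alternates and every HF-to-LF transition is an anchor.
simulate_state_lfp <- function(dur, rate, st, anchors) {
  n <- round(dur * rate)
  tt <- (seq_len(n) - 1) / rate
  ny <- rate / 2
  lf_x <- signal::filtfilt(signal::butter(3, st$lf_band / ny, type = "pass"),
                           rnorm(n))
  hf_x <- signal::filtfilt(signal::butter(3, st$hf_band / ny, type = "pass"),
                           rnorm(n))
  lf_x <- lf_x / sd(lf_x)
  hf_x <- hf_x / sd(hf_x)
  in_hf <- rep(FALSE, n)
  if (length(anchors)) {
    hf_starts <- numeric(length(anchors))
    prev_end <- 0
    for (i in seq_along(anchors)) {
      lo <- prev_end + 2
      hi <- anchors[i] - 4
      hf_starts[i] <- if (hi > lo) runif(1, lo, hi) else lo
      in_hf[tt >= hf_starts[i] & tt < anchors[i]] <- TRUE
      prev_end <- anchors[i]
    }
  } else {
    # no planted coupling: alternate on exponential epochs
    t0 <- 0; state_hf <- FALSE
    while (t0 < dur) {
      len <- rexp(1, 1 / st$mean_epoch_s)
      if (state_hf) in_hf[tt >= t0 & tt < t0 + len] <- TRUE
      t0 <- t0 + len
      state_hf <- !state_hf
    }
  }
  lf_gain <- ifelse(in_hf, 8, 30)
  hf_gain <- ifelse(in_hf, 12, 4)
  # soften gain switches over ~0.25 s to avoid broadband clicks
  sm <- round(0.25 * rate)
  if (sm > 1) {
    lf_gain <- moving_average(lf_gain, sm)
    hf_gain <- moving_average(hf_gain, sm)
  }
  volt <- lf_gain * lf_x + hf_gain * hf_x + 5 * powerlaw_noise(n, 1)
  new_lfp_recording(volt, rate)
}

#' Simulate a wheel optoswitch voltage trace
#'
#' Emits a binary-toggling voltage in which circuit breaks occur at
#' `speed / tab_spacing_cm` per second, evenly spaced within each second,
#' so that [compute_wheel_speed()] can recover the planted speed.
#'
#' @param speed speed trace in cm/s, sampled at 1 Hz.
#' @param rate output voltage sampling rate in Hz.
#' @param tab_spacing_cm distance between wheel tabs in cm.
#' @param v_high high voltage level.
#' @return numeric voltage trace of length `length(speed) * rate`.
#' @export
simulate_wheel_voltage <- function(speed, rate = 1000, tab_spacing_cm = 2,
                                   v_high = 5) {
  n <- length(speed) * rate
  breaks <- numeric(0)
  for (s in seq_along(speed)) {
    nb <- round(speed[s] / tab_spacing_cm)
    if (nb > 0) {
      breaks <- c(breaks, (s - 1) + (seq_len(nb) - 0.5) / nb)
    }
  }
  v <- numeric(n)
  level <- 0
  idx <- sort(round(breaks * rate) + 1L)
  prev <- 1L
  for (i in idx) {
    v[prev:(i - 1L)] <- level
    level <- v_high - level
    prev <- i
  }
  v[prev:n] <- level
  v
}
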