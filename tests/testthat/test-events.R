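test_that("event filtering enforces each rule, is idempotent and monotone", {
  tab <- data.frame(
    onset_frame = 1:7, offset_frame = c(4, 4, 1:4, 10) + 1:7,
    area_um2 = c(15, 5, 15, 15, 15, 10, 40),
    significance = c(0.01, 0.01, 0.01, 0.2, 0.04, 0.01, 0.01)
  )
  tab$offset_frame <- tab$onset_frame + c(3, 3, 0, 3, 3, 3, 3)
  kept <- filter_astro_events(tab)
  # rows 2 (area), 3 (duration), 4 (p), 6 (area not > 10) fail
  expect_equal(kept$onset_frame, c(1L, 5L, 7L))
  expect_identical(filter_astro_events(kept), kept)
  # tightening any threshold can only shrink the set
  expect_lte(nrow(filter_astro_events(tab, min_area_um2 = 20)), nrow(kept))
  expect_lte(nrow(filter_astro_events(tab, min_frames = 5)), nrow(kept))
  expect_lte(nrow(filter_astro_events(tab, max_p = 0.005)), nrow(kept))
  expect_error(filter_astro_events(tab[, -3]), "area_um2")
})

test_that("population fluorescence is max-normalized, idempotent under duplication, bounded", {
  x <- c(0, 1, 3, 2)
  expect_equal(population_fluorescence(rbind(x)), x / 3)
  expect_equal(population_fluorescence(rbind(x, x)), x / 3)
  y <- rbind(2 * x, 4 * x)
  out <- population_fluorescence(y)
  expect_equal(max(out), 1)
  expect_true(all(out >= 0 & out <= 1))
  expect_warning(population_fluorescence(rbind(x, rep(0, 4))), "all-zero")
})

test_that("neuronal event thresholding matches the normal tail on Gaussian noise", {
  expect_length(detect_neuronal_events(rep(2, 100)), 0L)
  tr <- rep(0.01, 500)
  tr[250] <- 10
  ev <- detect_neuronal_events(tr, rate = 2)
  expect_equal(ev, (250 - 1) / 2)
  set.seed(11)
  x <- rnorm(2e5)
  rate_emp <- length(detect_neuronal_events(x)) / length(x)
  expect_equal(rate_emp, pnorm(3, lower.tail = FALSE), tolerance = 0.25)
})

test_that("event-triggered averages recover periodic structure and white-noise s.e.m.", {
  rate <- 10
  period <- 4
  t <- (0:2399) / rate
  x <- sin(2 * pi * t / period)
  events <- seq(20, 200, by = period * 5)
  eta <- event_triggered_average(x, rate, events, window = c(2, 2))
  expect_equal(eta$mean, sin(2 * pi * (events[1] + eta$times_s) / period),
               tolerance = 1e-9)
  expect_equal(max(eta$sem), 0, tolerance = 1e-9)

  set.seed(3)
  noise <- rnorm(24000)
  ev2 <- runif(100, 10, 2300)
  eta2 <- event_triggered_average(noise, rate, ev2, window = c(1, 1))
  expect_equal(mean(eta2$sem), 1 / sqrt(eta2$n_events), tolerance = 0.15)

  expect_warning(
    one <- event_triggered_average(noise, rate, 100, window = c(1, 1)),
    "single event")
  expect_equal(one$sem, rep(0, length(one$mean)))
  expect_equal(one$n_events, 1L)
  expect_error(event_triggered_average(noise, rate, 1e6, window = c(1, 1)),
               "no events")
})

test_that("cross-correlation sign convention, symmetry, and null envelope", {
  set.seed(4)
  x <- as.numeric(arima.sim(list(ar = 0.9), 2000))
  cc0 <- cross_correlate(x, x, rate_x = 10, rate_target = 10, max_lag_s = 5)
  expect_equal(cc0$peak_lag_s, 0)
  expect_equal(cc0$peak_r, 1, tolerance = 1e-9)

  # y delayed 2 s: x leads, peak at -2 s
  y <- c(rep(NA, 20), x[1:(2000 - 20)])
  y[is.na(y)] <- 0
  ccd <- cross_correlate(x, y, rate_x = 10, rate_target = 10, max_lag_s = 5)
  expect_equal(ccd$peak_lag_s, -2, tolerance = 0.101)

  # antisymmetry under argument swap
  z <- as.numeric(arima.sim(list(ar = 0.5), 2000))
  ab <- cross_correlate(x, z, rate_x = 10, rate_target = 10, max_lag_s = 3)
  ba <- cross_correlate(z, x, rate_x = 10, rate_target = 10, max_lag_s = 3)
  expect_equal(ab$r, rev(ba$r), tolerance = 1e-9)

  # independent white noise stays inside the null envelope
  set.seed(5)
  peaks <- replicate(20, {
    cross_correlate(rnorm(500), rnorm(500), rate_x = 10, rate_target = 10,
                    max_lag_s = 2)$peak_r
  })
  expect_lt(median(abs(peaks)), 3 * 2 / sqrt(500))
})

test_that("decile binning partitions samples and tracks monotone coupling", {
  set.seed(6)
  p <- runif(5000)
  out <- pupil_decile_binning(p, p)
  expect_equal(sum(out$n), 5000L)
  expect_true(all(abs(out$n - 500) <= 5))
  expect_true(all(diff(out$mean_signal) > 0))
  expect_error(pupil_decile_binning(rep(0.5, 100), rnorm(100)), "constant")
})

test_that("NE peak detection classifies prominence and measures width", {
  rate <- 2
  t <- (0:999) / rate
  expect_equal(nrow(detect_ne_peaks(rep(0, 1000) + 1e-9 * t, rate)), 0L)

  # single smooth bump on a tiny-noise baseline; small noise peaks are
  # removed by a 3-s.d. prominence threshold
  set.seed(7)
  base <- rnorm(1000, sd = 0.02)
  bump <- 1 * exp(-(t - 250)^2 / 18)
  pk <- detect_ne_peaks(base + bump, rate, min_prominence_sd = 3)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$time_s, 250, tolerance = 1)
  expect_equal(pk$class, floor(pk$amplitude_sd))
  # width at half prominence of a Gaussian: 2*sqrt(2 ln 2)*sigma = 2.355*3
  expect_equal(pk$duration_s, 2.355 * 3, tolerance = 0.8)
})

test_that("planted phasic NE classes have durations increasing with amplitude", {
  cfg <- default_cfg(seed = 13, duration_s = 900, ne_phasic_rate = 6)
  sim <- simulate_session(cfg)
  pk <- detect_ne_peaks(sim$bundle$ne, cfg$rates$imaging)
  pk <- pk[pk$class >= 1 & pk$class <= 3, ]
  med <- tapply(pk$duration_s, pmin(pk$class, 3), median)
  expect_gte(length(med), 2)
  expect_true(all(diff(med) > 0))
})

test_that("event pupil phase labels onsets on dilations", {
  d <- c(seq(0.2, 0.8, length.out = 60), seq(0.8, 0.3, length.out = 60))
  p <- pupil_trace(d, rate = 30)
  lab <- event_pupil_phase(c(0.5), c(3), p)
  expect_equal(lab$onset_phase, "dilation")
  expect_equal(lab$offset_phase, "constriction")

  cfg <- default_cfg(seed = 14, duration_s = 600)
  sim <- simulate_session(cfg)
  p2 <- process_pupil(sim$bundle$pupil, cfg$rates$pupil)
  on <- sim$truth$dilation_onsets_s + 0.5  # just after the planted rise starts
  lab2 <- event_pupil_phase(on, on + 1, p2)
  expect_gte(mean(lab2$onset_phase == "dilation"), 0.9)
})

test_that("photometry preprocessing removes trends and the 5 Hz stopband", {
  rate <- 20
  t <- (0:1999) / rate
  out <- photometry_preprocess(5 - 0.01 * t, rate)  # pure bleaching ramp
  expect_lt(max(abs(out)), 1e-9)

  x <- sin(2 * pi * 0.2 * t) + 0.5 * sin(2 * pi * 5 * t)
  y <- photometry_preprocess(x, rate)
  zs <- (x - mean(x)) / sd(x)
  expect_lt(sine_amplitude(y, 5, rate) / sine_amplitude(zs, 5, rate), 0.05)
  # z-score contract holds before filtering: passband amplitude matches
  # the z-scored input
  expect_equal(sine_amplitude(y, 0.2, rate) / sine_amplitude(zs, 0.2, rate),
               1, tolerance = 0.05)
  expect_error(photometry_preprocess(rnorm(100), rate = 3), "4 Hz")
})

test_that("startle onset matches a numeric-differentiation oracle and is equivariant", {
  rate <- 20
  t <- (0:199) / rate
  k <- 3; t0 <- 5
  y <- 1 + 2 / (1 + exp(-k * (t - t0)))
  got <- startle_onset(y, rate)

  # oracle: 4th finite difference of the logistic on an independent grid,
  # earliest pre-midpoint extremum
  dt <- 0.01
  tg <- seq(0, 10, by = dt)
  yg <- 1 / (1 + exp(-k * (tg - t0)))
  d4 <- yg
  for (i in 1:4) d4 <- diff(d4)
  t_d4 <- tg[seq_along(d4)] + 2 * dt   # centers of the 4th differences
  dd <- diff(d4)
  flips <- which(dd[-1] * dd[-length(dd)] < 0) + 1L
  onset_oracle <- t_d4[flips[t_d4[flips] < t0][1]]
  expect_equal(got$onset_s, onset_oracle, tolerance = 0.02)

  # onset sits before the midpoint at an offset scaling as 1/k
  y2 <- 1 + 2 / (1 + exp(-2 * k * (t - t0)))
  got2 <- startle_onset(y2, rate)
  expect_equal(t0 - got2$onset_s, (t0 - got$onset_s) / 2, tolerance = 0.02)

  # pure time shift moves the onset by the same amount
  y3 <- 1 + 2 / (1 + exp(-k * (t - (t0 + 1))))
  expect_equal(startle_onset(y3, rate)$onset_s - got$onset_s, 1,
               tolerance = 0.01)
  expect_error(startle_onset(rev(y), rate), "rise")
})

test_that("startle onset is stable under noise across seeds", {
  rate <- 20
  t <- (0:199) / rate
  y <- 1 + 2 / (1 + exp(-3 * (t - 5)))   # amplitude 2, noise s.d. 0.2: SNR 10
  clean <- startle_onset(y, rate)$onset_s
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    startle_onset(y + rnorm(length(y), sd = 0.2), rate)$onset_s - clean
  }, numeric(1))
  expect_lt(median(abs(errs)), 2 / rate)
})
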