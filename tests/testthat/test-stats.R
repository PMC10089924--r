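make_nested <- function(n_mice, n_rec, n_obs, cond, mouse_sd = 1,
                        rec_sd = 1, obs_sd = 1, shift = 0) {
  do.call(rbind, lapply(seq_len(n_mice), function(m) {
    mu_m <- rnorm(1, 0, mouse_sd)
    do.call(rbind, lapply(seq_len(n_rec), function(r) {
      data.frame(value = shift + mu_m + rnorm(1, 0, rec_sd) +
                   rnorm(n_obs, 0, obs_sd),
                 mouse = paste0(cond, m),
                 recording = paste0(cond, m, "_", r),
                 condition = cond)
    }))
  }))
}

test_that("hierarchical bootstrap is seed-reproducible and centered for identical data", {
  set.seed(30)
  half <- make_nested(4, 3, 10, "a")
  dup <- half
  dup$condition <- "b"
  dup$mouse <- sub("^a", "b", dup$mouse)
  dup$recording <- sub("^a", "b", dup$recording)
  d <- rbind(half, dup)
  r1 <- hierarchical_bootstrap(d, n_resamples = 400, seed = 5)
  r2 <- hierarchical_bootstrap(d, n_resamples = 400, seed = 5)
  expect_identical(r1$distribution, r2$distribution)
  expect_identical(r1$p_value, r2$p_value)
  # identical conditions: p near 1/2 within Monte-Carlo error 3/sqrt(n)
  expect_equal(r1$p_value, 0.5, tolerance = 3 / sqrt(400))
  expect_equal(r1$observed, 0)
})

test_that("a large separation is detected and p-values are floored", {
  set.seed(31)
  d <- rbind(make_nested(4, 3, 10, "a"),
             make_nested(4, 3, 10, "b", shift = 10 * sqrt(3)))
  r <- hierarchical_bootstrap(d, n_resamples = 1000, seed = 6)
  expect_equal(r$p_value, 1e-3)  # floor at 1/n_resamples
  expect_equal(r$direction, "greater")
})

test_that("single-condition statistics and degenerate structures work", {
  set.seed(32)
  d <- make_nested(5, 2, 8, "a")
  r <- hierarchical_bootstrap(d, statistic = median, n_resamples = 200,
                              seed = 7)
  expect_length(r$distribution, 200)
  single <- d[d$mouse == "a1", ]
  expect_warning(hierarchical_bootstrap(single, n_resamples = 50, seed = 1),
                 "single mouse")
})

test_that("with one recording and one observation per mouse the bootstrap is flat", {
  set.seed(33)
  vals <- rnorm(12)
  d <- data.frame(value = vals, mouse = seq_along(vals),
                  recording = seq_along(vals))
  hb <- hierarchical_bootstrap(d, n_resamples = 2000, seed = 9)
  # flat bootstrap oracle for the mean of 12 values
  flat <- replicate(2000, mean(sample(vals, replace = TRUE)))
  expect_equal(mean(hb$distribution), mean(flat), tolerance = 0.05)
  expect_equal(sd(hb$distribution), sd(flat), tolerance = 0.1 * sd(flat))
  ks <- suppressWarnings(stats::ks.test(hb$distribution, flat))
  expect_gt(ks$p.value, 0.001)
})

test_that("paired bootstrap reproduces bit-exactly and discriminates planted effects", {
  set.seed(34)
  base <- rnorm(8, 10)
  sal_b <- rnorm(8, 10)
  sal_t <- sal_b + rnorm(8, 0, 1)

  # identical arms: non-significant
  r_null <- paired_bootstrap_effect(base, base + rnorm(8, 0, 0.2),
                                    sal_b, sal_t, seed = 11)
  expect_gt(r_null$p_value, 0.2)

  # effect far beyond saline extremes: floored p
  r_big <- paired_bootstrap_effect(base, base - 10 * sd(sal_t - sal_b),
                                   sal_b, sal_t, seed = 12)
  expect_equal(r_big$p_value, 1e-4)

  r_rep <- paired_bootstrap_effect(base, base - 10 * sd(sal_t - sal_b),
                                   sal_b, sal_t, seed = 12)
  expect_identical(r_big$p_value, r_rep$p_value)
  expect_identical(r_big$distribution, r_rep$distribution)
  expect_error(paired_bootstrap_effect(base, base, sal_b[1], sal_t[1]),
               ">= 2")
})

test_that("shuffled-onset nulls respect edges, counts, and circular invariance", {
  counts <- shuffled_event_null(100, 12, 20, analysis = length, edge_s = 5,
                                seed = 13)
  expect_equal(counts, rep(12, 20))

  times_ok <- shuffled_event_null(100, 10, 50,
                                  analysis = function(t) min(t), edge_s = 5,
                                  seed = 14)
  expect_true(all(times_ok >= 5))
  expect_error(shuffled_event_null(10, 5, 10, analysis = length,
                                   edge_s = 6), "window")

  # null distribution invariant (in distribution) to circularly shifting
  # the underlying signal
  set.seed(35)
  x <- as.numeric(arima.sim(list(ar = 0.95), 4000))
  xs <- c(x[1001:4000], x[1:1000])
  stat_for <- function(signal) {
    function(times) {
      idx <- pmax(1, pmin(4000, round(times * 10)))
      mean(signal[idx])
    }
  }
  n1 <- shuffled_event_null(400, 20, 150, stat_for(x), edge_s = 2, seed = 15)
  n2 <- shuffled_event_null(400, 20, 150, stat_for(xs), edge_s = 2, seed = 16)
  ks <- suppressWarnings(stats::ks.test(n1, n2))
  expect_gt(ks$p.value, 0.001)
})

test_that("planted LFP transitions beat the shuffled null; stationary noise does not", {
  cfg <- sim_config(duration_s = 300, seed = 24,
                    lfp_state = list(lf_band = c(2, 7), hf_band = c(70, 100),
                                     transition_coupling = 1,
                                     mean_epoch_s = 20))
  sim <- simulate_session(cfg)
  lfp <- sim$bundle$lfp_ipsi
  bp <- multitaper_bandpower(lfp, c(2, 7), window_s = 5, step_s = 1)
  ev <- sim$truth$state_transition_s
  ev <- ev[ev > 10 & ev < 290]
  emp <- median(band_change_around_events(bp, ev, window_s = 5)$ratio,
                na.rm = TRUE)
  null <- shuffled_event_null(300, length(ev), 100, function(times) {
    median(band_change_around_events(bp, times, window_s = 5)$ratio,
           na.rm = TRUE)
  }, edge_s = 6, seed = 17)
  expect_gt(emp, quantile(null, 0.95))

  # stationary noise control: empirical ratio inside the central 95%
  set.seed(36)
  flat <- preprocess_lfp(rnorm(300 * 1000), 1000)
  bp2 <- multitaper_bandpower(flat, c(2, 7), window_s = 5, step_s = 1)
  emp2 <- median(band_change_around_events(bp2, ev, window_s = 5)$ratio)
  null2 <- shuffled_event_null(300, length(ev), 100, function(times) {
    median(band_change_around_events(bp2, times, window_s = 5)$ratio)
  }, edge_s = 6, seed = 18)
  expect_gte(emp2, quantile(null2, 0.025))
  expect_lte(emp2, quantile(null2, 0.975))
})
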