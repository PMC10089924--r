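test_that("moving-average detrend zeroes constants and interior ramps", {
  expect_equal(detrend_moving_average(rep(5, 300)), rep(0, 300))
  ramp <- 0.3 * seq_len(300)
  res <- detrend_moving_average(ramp, 100)
  expect_equal(res[60:240], rep(0, 181), tolerance = 1e-10)
  expect_error(detrend_moving_average(rep(1, 50), 100), "longer")
})

test_that("detrend matches an explicit convolution oracle and passes fast, removes slow sinusoids", {
  set.seed(1)
  x <- rnorm(1000)
  res <- detrend_moving_average(x, 100)
  oracle <- x - oracle_moving_average_interior(x, 100)
  interior <- 51:950
  expect_equal(res[interior], oracle[interior], tolerance = 1e-12)

  rate <- 2
  t <- (0:999) / rate
  fast <- sin(2 * pi * 0.5 * t)     # period 2 s << 50 s window
  slow <- sin(2 * pi * 0.002 * t)   # period 500 s >> window
  expect_gt(cor(detrend_moving_average(fast, 100)[interior], fast[interior]), 0.99)
  expect_lt(max(abs(detrend_moving_average(slow, 100)[interior])), 0.1)
})

test_that("vascular region selection finds the darkest connected block with deterministic ties", {
  arr <- array(10, c(150, 6, 6))
  arr[, 2:4, 2:4] <- 1  # uniformly darkest 3x3 block
  mv <- pixel_movie(arr, 2)
  ref <- select_vascular_reference(mv, region_size = 9)
  want <- sort(as.vector(outer((1:3) * 6, 2:4, "+")))  # rows 2-4, cols 2-4
  expect_equal(ref$pixel_idx, want)
  expect_equal(mean(ref$ref_curve), 0, tolerance = 1e-10)

  # two equally dark blocks: smallest flattened index wins
  arr2 <- array(10, c(150, 4, 8))
  arr2[, 1:2, 1:2] <- 1
  arr2[, 3:4, 7:8] <- 1
  ref2 <- select_vascular_reference(pixel_movie(arr2, 2), region_size = 4)
  expect_equal(ref2$pixel_idx, c(1L, 2L, 9L, 10L))
  expect_error(select_vascular_reference(mv, region_size = 2), "at least 4")
})

test_that("attenuation fit recovers exact log-linear pixels and nulls white noise", {
  set.seed(2)
  ref <- sin(2 * pi * 0.1 * (0:499) / 2) * 0.5
  ref <- ref - mean(ref)
  exact <- exp(2 * ref)              # strictly positive: used as-is
  noise <- rnorm(500) + 5
  fit <- fit_attenuation(rbind(exact, noise), ref)
  expect_equal(fit$a[1], 2, tolerance = 1e-10)
  expect_equal(fit$b[1], 0, tolerance = 1e-10)
  expect_equal(fit$fit_r2[1], 1, tolerance = 1e-10)
  expect_lt(abs(fit$a[2]), 0.2)
  expect_lt(fit$fit_r2[2], 0.05)
  expect_error(fit_attenuation(rbind(exact), rep(1, 500)), "degenerate")
})

test_that("gain recovery on a contaminated movie is accurate at low noise", {
  toy <- make_toy_movie(n_pixels = 100, n_frames = 600, noise_sd = 0.1,
                        f_const = 80, seed = 3)
  detr <- t(apply(movie_pixels(toy$movie), 1, detrend_moving_average,
                  window = 100))
  fit <- fit_attenuation(detr, detrend_moving_average(toy$h, 100),
                         offsets = rowMeans(movie_pixels(toy$movie)))
  expect_gt(cor(fit$a, toy$a), 0.95)
})

test_that("apply_correction is the exact inverse of the noiseless model", {
  toy <- make_toy_movie(n_pixels = 9, n_frames = 300, noise_sd = 0,
                        b = runif(9, -0.2, 0.2), seed = 4)
  fit <- hemo_fit(toy$a, toy$b, toy$h)
  corr <- apply_correction(toy$movie, fit)
  rel_err <- max(abs(corr$corrected_pixels - toy$f) / toy$f)
  expect_lt(rel_err, 1e-6)

  # identity when the fitted attenuation is zero
  fit0 <- hemo_fit(rep(0, 9), rep(0, 9), toy$h)
  corr0 <- apply_correction(toy$movie, fit0)
  expect_equal(corr0$corrected_pixels, movie_pixels(toy$movie))
})

test_that("reporter selection follows the percentile rule exactly", {
  fit <- hemo_fit(a = 0:99, b = 0, ref_curve = rep(0, 10))
  idx <- select_reporter_pixels(fit)
  expect_equal(idx, 2:25)        # ranks 2-25, 24 pixels
  expect_length(idx, 24)

  # ties broken by pixel index, size preserved
  fit_tie <- hemo_fit(a = rep(1, 200), b = 0, ref_curve = rep(0, 10))
  idx_tie <- select_reporter_pixels(fit_tie)
  expect_equal(idx_tie, 3:50)    # floor(0.01*200)=2 excluded, up to rank 50
  expect_length(idx_tie, floor(0.25 * 200) - floor(0.01 * 200))
  expect_error(select_reporter_pixels(hemo_fit(a = 1:50, b = 0,
                                               ref_curve = rep(0, 4))),
               "fewer than 100")
})

test_that("mask size obeys floor(0.25 n) - floor(0.01 n) for assorted n", {
  for (n in c(100, 101, 137, 250, 999)) {
    fit <- hemo_fit(a = seq_len(n), b = 0, ref_curve = rep(0, 4))
    expect_length(select_reporter_pixels(fit),
                  floor(0.25 * n) - floor(0.01 * n))
  }
})

test_that("final signal is the reporter mean and scale-equivariant", {
  toy <- make_toy_movie(n_pixels = 9, n_frames = 300, noise_sd = 0, seed = 5)
  fit <- hemo_fit(toy$a, toy$b, toy$h)
  corr <- apply_correction(toy$movie, fit)
  one <- corrected_grabne_signal(corr, 3L)
  expect_equal(one$final_trace, corr$corrected_pixels[3, ])
  expect_error(corrected_grabne_signal(corr, integer(0)), "empty")

  # global scaling of the movie scales the final trace identically
  sc <- pixel_movie(toy$movie$data * 7, toy$movie$frame_rate)
  corr_sc <- corrected_grabne_signal(apply_correction(sc, fit), c(1L, 4L))
  base <- corrected_grabne_signal(corr, c(1L, 4L))
  expect_equal(corr_sc$final_trace, 7 * base$final_trace, tolerance = 1e-12)
})

test_that("refinement degenerates correctly and improves a contaminated reference", {
  # one pixel with weight, rest zero: reference is that pixel's detrended
  # relative curve
  toy <- make_toy_movie(n_pixels = 9, n_frames = 300, noise_sd = 0, seed = 6)
  fit <- hemo_fit(c(1, rep(0, 8)), rep(0, 9), toy$h)
  out <- refine_reference(toy$movie, fit, n_iter = 1)
  px1 <- movie_pixels(toy$movie)[1, ]
  expect_equal(out$ref$ref_curve,
               detrend_moving_average(px1 / mean(px1), 100),
               tolerance = 1e-10)
  expect_error(refine_reference(toy$movie,
                                hemo_fit(rep(0, 9), rep(0, 9), toy$h),
                                n_iter = 1),
               "weights")

  # identical pixels: refined reference is the shared detrended relative
  # curve regardless of weights
  arr2 <- array(0, c(300, 2, 2))
  for (i in 1:2) for (j in 1:2) arr2[, i, j] <- 100 + 10 * sin((1:300) / 10)
  mv2 <- pixel_movie(arr2, 2)
  fit2 <- hemo_fit(c(0.2, 0.5, 0.9, 0.1), rep(0, 4), toy$h[1:300])
  out2 <- refine_reference(mv2, fit2, n_iter = 1)
  common <- detrend_moving_average(arr2[, 1, 1] / mean(arr2[, 1, 1]), 100)
  expect_equal(out2$ref$ref_curve, common, tolerance = 1e-10)
})

test_that("full pipeline recovers the true signal on a synthetic session", {
  cfg <- sim_config(duration_s = 700, seed = 21,
                    hemo = list(n_pixels = 100, gain_range = c(0.1, 0.8),
                                offset_range = c(-0.1, 0.1), noise_sd = 0.6))
  sim <- simulate_session(cfg, make_movie = TRUE)
  res <- correct_hemodynamics(sim$bundle$movie)
  np <- nrow(sim$truth$F_true)
  f_mean <- colMeans(sim$truth$F_true)
  raw_mean <- colMeans(movie_pixels(sim$bundle$movie)[seq_len(np), ])
  expect_gt(cor(res$final_trace, f_mean), 0.95)
  expect_gt(cor(res$fit$a[seq_len(np)], sim$truth$hemo_a_true), 0.95)
  expect_gt(cor(res$final_trace, f_mean) - cor(raw_mean, f_mean), 0.1)
  # selected region sits inside the planted vascular block
  expect_gte(mean(res$initial_reference$pixel_idx %in%
                    sim$truth$vascular_idx), 0.8)
  # reporters are less attenuated than average
  rep_in <- res$reporter_mask[res$reporter_mask <= np]
  expect_lt(mean(sim$truth$hemo_a_true[rep_in]),
            mean(sim$truth$hemo_a_true))
})

test_that("pixelwise regressor correlation flags vascular pixels and handles degenerate traces", {
  cfg <- sim_config(duration_s = 500, seed = 22,
                    hemo = list(n_pixels = 64, gain_range = c(0.1, 0.8),
                                offset_range = c(-0.05, 0.05), noise_sd = 0.6))
  sim <- simulate_session(cfg, make_movie = TRUE)
  ne_img <- sim$bundle$ne
  cmap <- pixelwise_regressor_correlation(sim$bundle$movie, ne_img)
  np <- nrow(sim$truth$F_true)
  vasc <- sim$truth$vascular_idx
  expect_gt(mean(cmap[setdiff(seq_len(np), vasc)]), mean(cmap[vasc]))

  m <- rbind(ne_img, -ne_img, rep(1, length(ne_img)))
  r <- pixelwise_regressor_correlation(m, ne_img)
  expect_equal(r[1:2], c(1, -1), tolerance = 1e-12)
  expect_true(is.na(r[3]))
})
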