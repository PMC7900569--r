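fm <- toy_forward_model(n_sensors = 24, sources_per_cell = 2)

test_that("coherence-prior inversion is linear and zero-preserving", {
  b <- matrix(0, nrow = 24, ncol = 100)
  expect_true(all(invert_coherent(b, fm) == 0))
  set.seed(1)
  b1 <- matrix(rnorm(24 * 100), nrow = 24)
  j1 <- invert_coherent(b1, fm)
  expect_equal(invert_coherent(2 * b1, fm), 2 * j1, tolerance = 1e-10)
  expect_error(invert_coherent(b1, fm, lambda_reg = 0), "lambda_reg")
  expect_error(invert_coherent(matrix(0, 5, 10), fm), "channels")
})

test_that("noiseless single-source data localize to the true source", {
  # forward-simulate each candidate source; the reconstructed variance
  # maximum must land on the active source (well-separated toy grid)
  t <- seq(0, 1, by = 1 / 250)
  s <- sin(2 * pi * 8 * t)
  hits <- vapply(seq_len(ncol(fm$gain)), function(src) {
    b <- fm$gain[, src, drop = FALSE] %*% matrix(s, nrow = 1)
    j <- invert_coherent(b, fm)
    which.max(apply(j, 1, stats::var)) == src
  }, logical(1))
  expect_true(all(hits))
})

test_that("Morlet band power behaves as a quadratic narrow-band energy", {
  fs <- 500
  t <- (0:(4 * fs - 1)) / fs
  x <- sin(2 * pi * 10 * t)
  expect_equal(morlet_band_power(rep(0, 2000), "alpha", fs), 0)
  p_alpha <- morlet_band_power(x, "alpha", fs)
  p_beta <- morlet_band_power(x, "beta", fs)
  expect_gt(p_alpha / p_beta, 10)
  # closed-form oracle: an L1-normalized Morlet at frequency f responds to
  # a unit sinusoid at f0 with amplitude exp(-2 pi^2 sd_t^2 (f-f0)^2), and
  # |coef| = amplitude / 2; band power averages the squared response over
  # the 1-Hz in-band grid
  oracle <- mean(sapply(8:12, function(f) {
    sd_t <- 7 / (2 * pi * f)
    (0.5 * exp(-2 * pi^2 * sd_t^2 * (f - 10)^2))^2
  }))
  expect_equal(p_alpha, oracle, tolerance = 0.02)
  expect_equal(morlet_band_power(3 * x, "alpha", fs), 9 * p_alpha,
               tolerance = 1e-8)
  expect_error(morlet_band_power(x[1:100], "delta", fs), "too short")
})

test_that("trial averaging is an element-wise mean, order-invariant", {
  trials <- list(c(0, 1, 4), c(2, 3, 0))
  img <- average_trials(trials, band = "theta")
  expect_equal(img$power, c(1, 2, 2))
  expect_equal(img$n_trials_averaged, 2)
  expect_equal(average_trials(rev(trials))$power, img$power)
  one <- average_trials(trials[1])
  expect_equal(one$power, trials[[1]])
  expect_error(average_trials(list()), "no trials")
  expect_error(average_trials(list(1:2, 1:3)), "differing")
})

test_that("regional summaries equal a brute-force group-by mean", {
  n_src <- ncol(fm$gain)
  expect_equal(summarize_regions(rep(1, n_src), fm, band = "delta")$power,
               rep(1, 8))
  set.seed(2)
  img <- runif(n_src)
  got <- summarize_regions(img, fm, band = "alpha")
  key <- paste(fm$region_labels, fm$hemisphere_labels)
  oracle <- tapply(img, key, mean)
  expect_equal(got$power,
               as.numeric(oracle[paste(got$region, got$hemisphere)]))
  # bounded by member extremes
  expect_true(all(got$power >= min(img) & got$power <= max(img)))
  # targeted power shows up only in its own cell
  tgt <- as.numeric(fm$region_labels == "temporal" &
                      fm$hemisphere_labels == "L") * 2
  got2 <- summarize_regions(tgt, fm, band = "theta")
  expect_equal(got2$power[got2$region == "temporal" & got2$hemisphere == "L"], 2)
  expect_equal(sum(got2$power), 2)
})

test_that("a left-temporal theta source lateralizes the regional power table", {
  src_idx <- which(fm$region_labels == "temporal" &
                     fm$hemisphere_labels == "L")[1]
  hits <- vapply(1:5, function(s) {
    rec <- simulate_recording(
      n_channels = 24, duration_s = 10, fm = fm,
      components = tibble::tibble(freq_hz = 6, amplitude_ft = 500,
                                  source = src_idx),
      utility_hz = 50, utility_amplitude_ft = 50, noise_sd_ft = 10, seed = s)
    ep <- notch_filter(reject_epochs(segment_epochs(rec)))
    pt <- source_band_power(ep, fm, bands = meg_bands()[2, ])
    pt$power[pt$region == "temporal" & pt$hemisphere == "L"] >
      pt$power[pt$region == "temporal" & pt$hemisphere == "R"]
  }, logical(1))
  expect_true(all(hits))
})
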