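make_rec <- function(data, fs = 1000, utility = 50) {
  meglaterality:::new_recording(data, fs, utility)
}

sine_rec <- function(freq, duration = 10, fs = 1000, amp = 1, channels = 2) {
  t <- (seq_len(duration * fs) - 1) / fs
  make_rec(matrix(rep(amp * sin(2 * pi * freq * t), each = channels),
                  nrow = channels), fs)
}

test_that("segmentation follows the floor rule", {
  rec <- make_rec(matrix(rnorm(2 * 300 * 100), nrow = 2), fs = 100)
  expect_length(segment_epochs(rec)$epochs, 30)          # 300 s / 10 s
  rec2 <- make_rec(matrix(rnorm(2 * 305 * 100), nrow = 2), fs = 100)
  ep2 <- segment_epochs(rec2)
  expect_length(ep2$epochs, 30)                          # 5 s remainder dropped
  expect_true(all(vapply(ep2$epochs, ncol, integer(1)) == 1000))
  rec3 <- make_rec(matrix(rnorm(2 * 10 * 100), nrow = 2), fs = 100)
  ep3 <- segment_epochs(rec3)
  expect_length(ep3$epochs, 1)
  expect_equal(ep3$epochs[[1]], rec3$data)               # identity case
  expect_error(segment_epochs(make_rec(matrix(0, 2, 50), fs = 100)),
               "shorter than one epoch")
})

test_that("rejection uses any-channel any-sample absolute exceedance", {
  d <- matrix(5999, nrow = 2, ncol = 3000)
  ep <- segment_epochs(make_rec(d, fs = 100))
  expect_length(reject_epochs(ep)$epochs, 3)             # below threshold
  d[2, 1500] <- -6001                                    # epoch 2, one sample
  ep <- segment_epochs(make_rec(d, fs = 100))
  kept <- reject_epochs(ep)
  expect_identical(kept$kept_indices, c(1L, 3L))
  expect_error(reject_epochs(ep, threshold_ft = 100), "all epochs rejected")
  expect_error(reject_epochs(ep, threshold_ft = -1), "must be > 0")
})

test_that("segment then reject is idempotent on clean data", {
  rec <- make_rec(matrix(rnorm(2 * 3000, sd = 100), nrow = 2), fs = 100)
  ep <- reject_epochs(segment_epochs(rec))
  expect_identical(reject_epochs(ep)$kept_indices, ep$kept_indices)
  expect_equal(reject_epochs(ep)$epochs, ep$epochs)
})

test_that("notch filter removes the line frequency and spares the passband", {
  ep50 <- segment_epochs(sine_rec(50))
  out <- notch_filter(ep50, 50)
  expect_lt(rms(out$epochs[[1]][1, ]), 0.1 * rms(ep50$epochs[[1]][1, ]))

  ep10 <- segment_epochs(sine_rec(10))
  out10 <- notch_filter(ep10, 50)
  expect_lt(abs(rms(out10$epochs[[1]][1, ]) / rms(ep10$epochs[[1]][1, ]) - 1),
            0.12)

  zero <- segment_epochs(make_rec(matrix(0, 2, 10000)))
  expect_equal(notch_filter(zero, 50)$epochs[[1]], zero$epochs[[1]])
})

test_that("bandpass keeps in-band and rejects out-of-band sinusoids", {
  ep <- segment_epochs(sine_rec(10))
  in_band <- bandpass_filter(ep, "alpha")
  expect_lt(abs(rms(in_band$epochs[[1]][1, ]) / rms(ep$epochs[[1]][1, ]) - 1),
            0.12)
  out_band <- bandpass_filter(ep, "beta")
  expect_lt(rms(out_band$epochs[[1]][1, ]), 0.1 * rms(ep$epochs[[1]][1, ]))
  zero <- segment_epochs(make_rec(matrix(0, 2, 10000)))
  expect_equal(bandpass_filter(zero, "alpha")$epochs[[1]],
               zero$epochs[[1]])
  expect_error(bandpass_filter(segment_epochs(sine_rec(10, fs = 200)), "hfo"),
               "Nyquist")
})

test_that("filters are linear and never change epoch count or shape", {
  set.seed(5)
  x <- make_rec(matrix(rnorm(2 * 10000), nrow = 2))
  y <- make_rec(matrix(rnorm(2 * 10000), nrow = 2))
  a <- 2.5; b <- -1.25
  comb <- make_rec(a * x$data + b * y$data)
  for (f in list(function(e) notch_filter(e, 50),
                 function(e) bandpass_filter(e, "alpha"))) {
    fx <- f(segment_epochs(x))$epochs[[1]]
    fy <- f(segment_epochs(y))$epochs[[1]]
    fc <- f(segment_epochs(comb))$epochs[[1]]
    # linear up to float rounding, which the stiff narrow-band IIR
    # recursion amplifies well beyond machine epsilon
    expect_lt(max(abs(fc - (a * fx + b * fy))), 1e-3 * max(abs(fc)))
    expect_identical(dim(fc), dim(x$data))
  }
})
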