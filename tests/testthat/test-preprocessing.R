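test_that("downsampling preserves duration and passband content", {
  x <- matrix(rnorm(2 * 30000), 2, 30000)  # 60 s at 500 Hz
  y <- downsample(x, 500, 128)
  expect_equal(dim(y), c(2, 7680))

  expect_identical(downsample(x, 500, 500), x)
  expect_error(downsample(x, 100, 128), class = "invalid_argument")

  # a pure 5 Hz tone keeps its spectral peak within 0.2 Hz
  tt <- (0:29999) / 500
  tone <- sin(2 * pi * 5 * tt)
  yt <- downsample(tone, 500, 128)
  sp <- stats::spec.pgram(stats::ts(yt, frequency = 128), plot = FALSE,
                          taper = 0)
  expect_lt(abs(sp$freq[which.max(sp$spec)] - 5), 0.2)
  expect_lt(abs(stats::sd(yt) / stats::sd(tone) - 1), 0.05)

  # content above the output Nyquist is attenuated by >= 20 dB
  hi <- sin(2 * pi * 100 * tt)
  yh <- downsample(hi, 500, 128)
  expect_lt(20 * log10(stats::sd(yh) / stats::sd(hi)), -20)
})

test_that("bandpass meets its attenuation and flatness contracts", {
  rate <- 128
  tt <- (0:(rate * 30 - 1)) / rate
  mix <- sin(2 * pi * 2 * tt) + sin(2 * pi * 10 * tt)
  y <- bandpass(mix, rate)
  p2_in <- band_power(mix, rate, 1.5, 2.5)
  p10_in <- band_power(mix, rate, 9.5, 10.5)
  p2_out <- band_power(y, rate, 1.5, 2.5)
  p10_out <- band_power(y, rate, 9.5, 10.5)
  # 2 Hz is suppressed by >= 20 dB relative to 10 Hz
  expect_lt(10 * log10((p2_out / p10_out) / (p2_in / p10_in)), -20)

  expect_equal(bandpass(matrix(0, 3, 256), rate), matrix(0, 3, 256))

  tone10 <- sin(2 * pi * 10 * tt)
  y10 <- bandpass(tone10, rate)
  expect_lt(abs(stats::sd(y10) / stats::sd(tone10) - 1), 0.1)

  # band-pass never increases total power
  set.seed(4)
  noise <- matrix(rnorm(2 * 4096), 2, 4096)
  yn <- bandpass(noise, rate)
  expect_lt(sum(yn^2), sum(noise^2))

  expect_error(bandpass(mix, rate, low = 0), class = "invalid_argument")
  expect_error(bandpass(mix, rate, low = 4, high = 70),
               class = "invalid_argument")
})

test_that("channel reordering is a pure permutation of rows", {
  s <- fixture_session()
  same <- reorder_channels(s, s$channel_labels)
  expect_identical(same$data, s$data)

  swapped_order <- s$channel_labels
  swapped_order[1:2] <- swapped_order[2:1]
  sw <- reorder_channels(s, swapped_order)
  expect_identical(sw$data[1, ], s$data[2, ])
  expect_identical(sw$data[2, ], s$data[1, ])
  expect_identical(sw$data[3:32, ], s$data[3:32, ])

  set.seed(9)
  perm_order <- sample(s$channel_labels)
  round_trip <- reorder_channels(reorder_channels(s, perm_order),
                                 s$channel_labels)
  expect_identical(round_trip$data, s$data)

  bad <- s$channel_labels
  bad[1] <- "Xx9"
  expect_error(reorder_channels(s, bad), class = "channel_mismatch")
  expect_error(reorder_channels(s, rep(s$channel_labels[1], 32)),
               class = "channel_mismatch")
})

test_that("slicing recovers the eighteen playback segments", {
  s <- fixture_session()
  labels <- default_clip_labels()
  sliced <- slice_trials(s, labels)
  expect_length(sliced$trials, 18)
  expect_equal(ncol(sliced$trials[[1]]$data), 60 * 128)
  # trial 1 starts exactly at the code-2 marker
  start <- s$markers$sample_index[s$markers$code == 2] + 1
  expect_identical(sliced$trials[[1]]$data[, 1], s$data[, start])
  expect_equal(sliced$trials[[5]]$keyword, labels$keyword[5])

  broken <- s
  broken$markers <- broken$markers[broken$markers$code != 36, ]
  err <- tryCatch(slice_trials(broken, labels), condition = identity)
  expect_s3_class(err, "protocol_violation")
  expect_match(conditionMessage(err), "36")
})

test_that("detrending removes linear drift exactly", {
  tt <- seq_len(1000)
  lines <- rbind(2 + 0.5 * tt, -3 - 0.01 * tt)
  expect_lt(max(abs(detrend(lines))), 1e-8)

  set.seed(11)
  clean <- matrix(rnorm(2 * 1000), 2, 1000)
  clean <- clean - rowMeans(clean)
  # remove any accidental linear component so input is its own fixed point
  clean <- detrend(clean)
  expect_lt(max(abs(detrend(clean) - clean)), 1e-6 * stats::sd(clean))

  tr <- fixture_preprocessed()$trials[[1]]
  rms <- sqrt(rowMeans(tr$data^2))
  expect_true(all(abs(rowMeans(tr$data)) < 1e-8 * rms))
})

test_that("the pipeline runs the stages in the documented order", {
  prep <- fixture_preprocessed()
  expect_identical(prep$stage_log,
                   c("downsample", "bandpass", "reorder", "slice", "detrend"))
  expect_length(prep$trials, 18)
  for (tr in prep$trials[c(1, 18)]) {
    expect_equal(dim(tr$data), c(32, 7680))
    expect_equal(tr$sample_rate, 128)
  }
})

test_that("pipeline output does not depend on the input channel order", {
  s <- fixture_session()
  set.seed(21)
  perm <- sample(32)
  s_perm <- s
  s_perm$data <- s$data[perm, ]
  s_perm$channel_labels <- s$channel_labels[perm]
  p1 <- fixture_preprocessed()
  p2 <- preprocess_session(s_perm, default_clip_labels())
  expect_equal(p1$trials[[3]]$data, p2$trials[[3]]$data, tolerance = 1e-12)
})
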