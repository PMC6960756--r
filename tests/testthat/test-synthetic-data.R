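test_that("marker sequence follows the playback protocol", {
  m <- build_marker_sequence(18, rate = 500)
  expect_equal(nrow(m), 38)
  expect_equal(sort(m$code), 1:38)
  # start of playback n is code 2n, end is 2n + 1
  for (n in c(1, 5, 18)) {
    expect_equal(m$description[m$code == 2 * n],
                 sprintf("start of video playback %d", n))
    expect_equal(m$description[m$code == 2 * n + 1],
                 sprintf("end of video playback %d", n))
  }
  expect_equal(m$description[m$code == 36], "start of video playback 18")
  # 3000 ms baseline at 500 Hz puts the first playback at sample 1500
  expect_equal(m$sample_index[m$code == 2], 1500)
  # indices increase with code
  expect_false(is.unsorted(m$sample_index[order(m$code)]))

  tiny <- build_marker_sequence(1, rate = 128)
  expect_equal(sort(tiny$code), 1:4)

  expect_error(build_marker_sequence(18, clip_ms = -1),
               class = "invalid_argument")
  expect_error(build_marker_sequence(0), class = "invalid_argument")
})

test_that("simulated sessions are deterministic and structurally valid", {
  cfg <- sim_config(seed = 11, native_rate = 128, n_subjects_per_group = 2)
  s1 <- simulate_session(cfg, "s01", "photograph")
  s2 <- simulate_session(cfg, "s01", "photograph")
  expect_identical(s1$data, s2$data)
  expect_identical(s1$markers, s2$markers)

  expect_equal(nrow(s1$data), 32)
  total_ms <- cfg$baseline_ms + cfg$n_clips * (cfg$clip_ms + cfg$gap_ms)
  expect_equal(ncol(s1$data), round(total_ms * cfg$native_rate / 1000))
  expect_true(all(s1$markers$sample_index < ncol(s1$data)))
  expect_setequal(s1$channel_labels, deap_channel_order())

  expect_error(simulate_session(cfg, "s01", "tv"), class = "invalid_argument")
  expect_error(
    simulate_session(cfg, "s01", "artwork",
                     default_clip_labels()[1:6, ]),
    class = "invalid_argument"
  )
})

test_that("a single active band concentrates spectral power in that band", {
  cfg <- sim_config(
    seed = 3, native_rate = 128, n_subjects_per_group = 2,
    class_band_powers = list(
      valence_pos = c(theta = 1, alpha = 1, beta = 1, gamma = 1),
      valence_neg = c(theta = 1, alpha = 1, beta = 1, gamma = 1),
      arousal_pos = c(theta = 1, alpha = 1, beta = 1, gamma = 1),
      arousal_neg = c(theta = 1, alpha = 1, beta = 1, gamma = 1)
    ),
    noise = list(exponent = 1, amplitude = 0),
    band_amplitude_uv = c(theta = 0, alpha = 6, beta = 0, gamma = 0)
  )
  tr <- simulate_deap_trials(cfg, "p1", trials_each = 1)[[1]]
  x <- tr$data[1, ]
  in_band <- band_power(x, 128, 8, 13)
  out_band <- band_power(x, 128, 15, 45)
  expect_gt(in_band / out_band, 100)
})

test_that("class band-power structure is recoverable by a threshold classifier", {
  cfg <- sim_config(seed = 21, native_rate = 128, n_subjects_per_group = 2)
  trials <- simulate_deap_trials(cfg, c("p1", "p2"), trials_each = 10)
  alpha <- vapply(trials, function(tr) {
    mean(vapply(seq_len(8), function(c) band_power(tr$data[c, ], 128, 8, 13),
                numeric(1)))
  }, numeric(1))
  labs <- vapply(trials, `[[`, integer(1), "valence_label")
  thr <- mean(c(mean(alpha[labs > 0]), mean(alpha[labs < 0])))
  acc <- mean((alpha > thr) == (labs > 0))
  expect_gt(acc, 0.9)
})

test_that("response tables recover configured group effects", {
  null_cfg <- sim_config(seed = 31, n_subjects_per_group = 1000)
  tab0 <- simulate_response_tables(null_cfg)
  diff0 <- abs(mean(tab0$valence[tab0$group == "artwork"]) -
                 mean(tab0$valence[tab0$group == "photograph"]))
  expect_lt(diff0, 0.2)

  eff_cfg <- sim_config(seed = 31, n_subjects_per_group = 1000,
                        valence_effect_size = 1.2)
  tab1 <- simulate_response_tables(eff_cfg)
  for (kw in unique(tab1$keyword)) {
    ph <- tab1$valence[tab1$group == "photograph" & tab1$keyword == kw]
    aw <- tab1$valence[tab1$group == "artwork" & tab1$keyword == kw]
    d <- (mean(aw) - mean(ph)) / sqrt((stats::var(ph) + stats::var(aw)) / 2)
    expect_gt(d, 0.8)
    expect_lt(d, 1.6)
  }

  small <- simulate_response_tables(sim_config(seed = 1))
  expect_equal(length(unique(small$subject_id)), 40)
  expect_equal(nrow(small), 40 * 9)
  expect_true(all(small$valence >= -1 & small$valence <= 1))

  # determinism and substream order-independence
  expect_identical(simulate_response_tables(sim_config(seed = 5)),
                   simulate_response_tables(sim_config(seed = 5)))
})
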