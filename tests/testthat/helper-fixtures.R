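# Shared fixtures, built in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Small 128 Hz-native session (2 subjects would be wasteful; one is enough
# for structural tests).
fixture_session <- function() {
  cached("session", function() {
    cfg <- sim_config(seed = 101, native_rate = 128, n_subjects_per_group = 2)
    simulate_session(cfg, "fix01", "photograph")
  })
}

fixture_preprocessed <- function() {
  cached("preprocessed", function() {
    preprocess_session(fixture_session(), default_clip_labels())
  })
}

# Strongly class-separated config (9x alpha/beta power gap between the
# label extremes) for learnability tests.
separable_config <- function(seed = 77) {
  base <- c(theta = 1, alpha = 1, beta = 1, gamma = 1)
  sim_config(
    seed = seed, native_rate = 128, n_subjects_per_group = 2,
    class_band_powers = list(
      valence_pos = replace(base, "alpha", 3),
      valence_neg = replace(base, "alpha", 1 / 3),
      arousal_pos = replace(base, "beta", 3),
      arousal_neg = replace(base, "beta", 1 / 3)
    )
  )
}

fixture_separable_windows <- function() {
  cached("separable_windows", function() {
    cfg <- separable_config()
    spec <- window_spec(stride = 232)
    tr <- simulate_deap_trials(cfg, sprintf("tr%02d", 1:3), trials_each = 6)
    va <- simulate_deap_trials(cfg, sprintf("va%02d", 1:2), trials_each = 6)
    list(
      train = bind_window_sets(lapply(tr, extract_windows, spec = spec)),
      val = bind_window_sets(lapply(va, extract_windows, spec = spec))
    )
  })
}

fixture_trained_model <- function() {
  cached("trained_model", function() {
    ws <- fixture_separable_windows()
    tcfg <- train_config(k = 2, learning_rate = 0.3, max_epochs = 10,
                         seed = 5)
    train_recognizer(build_columns(tcfg, column_arch()), ws$train, ws$val)
  })
}

# Channel-pooled alpha-band power of one 32 x 32 window (periodogram over
# the 32-sample axis) -- the independent band-power oracle.
window_alpha_power <- function(w, rate = 128) {
  sp <- stats::mvfft(t(w))
  f <- (seq_len(nrow(sp)) - 1) * rate / nrow(sp)
  sel <- f >= 8 & f <= 13
  mean(Mod(sp[sel, , drop = FALSE])^2)
}

# Band power of a long single-channel signal via smoothed periodogram.
band_power <- function(x, rate, lo, hi) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = rate), plot = FALSE,
                          taper = 0, spans = 11)
  mean(sp$spec[sp$freq >= lo & sp$freq <= hi])
}
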