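#' Simulation configuration
#'
#' Bundles every parameter of the synthetic EEG study: cohort size, native
#' amplifier rate, the spectral class structure that encodes affect, the
#' background-noise model, and the standardized group effect sizes injected
#' on each affect axis.
#'
#' @param seed Root integer seed; all randomness fans out from it through
#'   counter-based substreams (see [substream_seed()]).
#' @param n_subjects_per_group Subjects per media group (default 20, the
#'   study cohort: twenty for photographs, twenty for artwork).
#' @param native_rate Native amplifier sampling rate in Hz (default 500,
#'   typical for a LiveAmp-class amplifier), so the 128 Hz downsample is a
#'   real operation. Must be at least 128.
#' @param class_band_powers Named list with elements `valence_pos`,
#'   `valence_neg`, `arousal_pos`, `arousal_neg`, each a named numeric
#'   vector of power multipliers for the theta/alpha/beta/gamma bands.
#'   Defaults encode valence in alpha power and arousal in beta power with
#'   a 4x power ratio between the label extremes.
#' @param noise Background-noise model: list with `exponent` (spectral
#'   slope of the 1/f background) and `amplitude` (RMS in microvolts).
#' @param channel_correlation Fraction of band-oscillation power carried
#'   by a source common to all 32 channels (default 0.7, mimicking the
#'   strong inter-channel correlation volume conduction produces in scalp
#'   EEG); the remainder and the 1/f background are channel-independent.
#' @param band_amplitude_uv Baseline RMS amplitude (microvolts) of each
#'   oscillatory band before class multipliers are applied.
#' @param valence_effect_size,arousal_effect_size Standardized mean shift
#'   (Cohen's d) of the artwork group relative to the photograph group on
#'   each affect axis.
#' @param response_sd Between-subject standard deviation of latent affect
#'   (and of simulated rating scores); the unit in which effect sizes are
#'   standardized.
#' @param baseline_ms,clip_ms,gap_ms,n_clips Session protocol: baseline
#'   length, playback length, post-playback gap (milliseconds) and number
#'   of clips. Defaults follow the marker protocol (3 s baseline, eighteen
#'   60 s playbacks, 5 s gaps).
#' @param keyword_table Keyword coordinate table (see [emotion_keywords()]).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_subjects_per_group = 20L,
                       native_rate = 500,
                       class_band_powers = default_band_powers(),
                       noise = list(exponent = 1, amplitude = 8),
                       channel_correlation = 0.7,
                       band_amplitude_uv = c(theta = 4, alpha = 6,
                                             beta = 3, gamma = 1.5),
                       valence_effect_size = 0,
                       arousal_effect_size = 0,
                       response_sd = 0.15,
                       baseline_ms = 3000,
                       clip_ms = 60000,
                       gap_ms = 5000,
                       n_clips = 18L,
                       keyword_table = emotion_keywords()) {
  if (n_subjects_per_group <= 1) {
    invalid_argument("n_subjects_per_group must be > 1")
  }
  if (native_rate < 128) invalid_argument("native_rate must be >= 128 Hz")
  if (channel_correlation < 0 || channel_correlation > 1) {
    invalid_argument("channel_correlation must lie in [0, 1]")
  }
  if (!is.finite(valence_effect_size) || !is.finite(arousal_effect_size)) {
    invalid_argument("effect sizes must be finite")
  }
  for (nm in c("valence_pos", "valence_neg", "arousal_pos", "arousal_neg")) {
    if (is.null(class_band_powers[[nm]])) {
      invalid_argument(sprintf("class_band_powers is missing '%s'", nm))
    }
  }
  structure(
    list(seed = as.integer(seed),
         n_subjects_per_group = as.integer(n_subjects_per_group),
         native_rate = native_rate,
         class_band_powers = class_band_powers,
         noise = noise,
         channel_correlation = channel_correlation,
         band_amplitude_uv = band_amplitude_uv,
         valence_effect_size = valence_effect_size,
         arousal_effect_size = arousal_effect_size,
         response_sd = response_sd,
         baseline_ms = baseline_ms,
         clip_ms = clip_ms,
         gap_ms = gap_ms,
         n_clips = as.integer(n_clips),
         keyword_table = keyword_table),
    class = "sim_config"
  )
}

#' Default per-label spectral power multipliers
#'
#' Positive valence doubles alpha power and negative valence halves it
#' (a 4x ratio across the label extremes); arousal does the same for beta.
#' Intermediate affect levels interpolate log-linearly, so the alpha
#' multiplier at latent valence v is `2^v`.
#'
#' @return Named list of per-band power multiplier vectors.
#' @export
default_band_powers <- function() {
  base <- c(theta = 1, alpha = 1, beta = 1, gamma = 1)
  list(
    valence_pos = replace(base, "alpha", 2.0),
    valence_neg = replace(base, "alpha", 0.5),
    arousal_pos = replace(base, "beta", 2.0),
    arousal_neg = replace(base, "beta", 0.5)
  )
}

# Oscillatory band edges (Hz).
eeg_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30), gamma = c(30, 45))
}

# Log-linear interpolation between the pos/neg multiplier profiles at a
# continuous affect level in [-1, 1]; multiplicative across the two axes.
band_multipliers <- function(valence, arousal, cbp) {
  v <- clamp(valence); a <- clamp(arousal)
  mv <- cbp$valence_pos^((1 + v) / 2) * cbp$valence_neg^((1 - v) / 2)
  ma <- cbp$arousal_pos^((1 + a) / 2) * cbp$arousal_neg^((1 - a) / 2)
  mv * ma
}

#' Native amplifier channel order
#'
#' The order in which the simulated 32-channel amplifier reports
#' electrodes (front-to-back sweep). A permutation of
#' [deap_channel_order()], so reordering to the DEAP montage is a real
#' preprocessing step.
#'
#' @return Character vector of 32 electrode labels.
#' @export
native_channel_order <- function() {
  c("Fp1", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
    "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
    "PO3", "PO4", "O1", "Oz", "O2")
}

#' Build the marker sequence for a recording session
#'
#' Produces the event-marker table of a complete session: code 1 at the
#' start of the baseline, code `2n` at the start of playback `n`, code
#' `2n + 1` at its end, and the final code `2 * n_clips + 2` at the last
#' recorded sample.
#'
#' @param n_clips Number of playbacks (default 18).
#' @param clip_ms,gap_ms,baseline_ms Segment durations in milliseconds.
#' @param rate Sampling rate in Hz used to place `sample_index`.
#' @return A data.frame with columns `code`, `sample_index` (0-based
#'   offset into the recording) and `description`, ordered by
#'   `sample_index`.
#' @export
#' @examples
#' m <- build_marker_sequence(18)
#' m[m$code == 36, ]  # start of video playback 18
build_marker_sequence <- function(n_clips = 18L, clip_ms = 60000,
                                  gap_ms = 5000, baseline_ms = 3000,
                                  rate = 500) {
  if (n_clips < 1) invalid_argument("n_clips must be >= 1")
  if (clip_ms <= 0 || gap_ms <= 0 || baseline_ms <= 0 || rate <= 0) {
    invalid_argument("durations and rate must be positive")
  }
  total_ms <- baseline_ms + n_clips * (clip_ms + gap_ms)
  n_total <- ms_to_samples(total_ms, rate)
  starts_ms <- baseline_ms + (seq_len(n_clips) - 1) * (clip_ms + gap_ms)
  ends_ms <- starts_ms + clip_ms
  events <- rbind(
    data.frame(code = 1L, sample_index = 0L,
               description = "start of baseline recording"),
    data.frame(code = 2L * seq_len(n_clips),
               sample_index = ms_to_samples(starts_ms, rate),
               description = sprintf("start of video playback %d",
                                     seq_len(n_clips))),
    data.frame(code = 2L * seq_len(n_clips) + 1L,
               sample_index = ms_to_samples(ends_ms, rate),
               description = sprintf("end of video playback %d",
                                     seq_len(n_clips))),
    data.frame(code = 2L * n_clips + 2L, sample_index = n_total - 1L,
               description = "end of recording")
  )
  events <- events[order(events$sample_index), ]
  rownames(events) <- NULL
  events
}

#' Default clip schedule
#'
#' Eighteen clips: each of the nine keywords once per medium, interleaved
#' (photograph then artwork within keyword). Every subject watches all
#' eighteen; analysis later keeps the clips of the subject's own medium.
#'
#' @param keyword_table Keyword table (defaults to [emotion_keywords()]).
#' @return A data.frame with 18 rows and columns `keyword`, `medium`.
#' @export
default_clip_labels <- function(keyword_table = emotion_keywords()) {
  kw <- keyword_table$keyword
  data.frame(
    keyword = rep(kw, each = 2),
    medium = rep(c("photograph", "artwork"), times = length(kw)),
    stringsAsFactors = FALSE
  )
}

# Spectrally shaped Gaussian segment: n x n_channels matrix containing a
# 1/f background plus band-limited oscillations with the given per-band RMS
# amplitudes. A fraction `rho` of the oscillatory power comes from a source
# shared by all channels (volume conduction); the rest, and the 1/f
# background, are independent per channel.
gen_eeg_segment <- function(n, rate, n_channels, band_rms_uv, noise,
                            rho = 0.7) {
  f <- (seq_len(n) - 1) * rate / n
  f_fold <- pmin(f, rate - f)            # folded (two-sided) frequency axis
  # background: |G|^2 ~ f^-exponent on [0.5 Hz, Nyquist], zero at DC
  g2_pink <- ifelse(f_fold >= 0.5, f_fold^(-noise$exponent), 0)
  if (sum(g2_pink) > 0) {
    g2_pink <- g2_pink * (n * noise$amplitude^2 / sum(g2_pink))
  }
  # band oscillations: flat in band with 1 Hz raised-cosine edges
  g2_osc <- numeric(n)
  bands <- eeg_bands()
  for (b in names(bands)) {
    lo <- bands[[b]][1]; hi <- bands[[b]][2]
    s <- numeric(n)
    inside <- f_fold >= lo & f_fold <= hi
    s[inside] <- 1
    edge <- f_fold > lo - 1 & f_fold < lo
    s[edge] <- 0.5 * (1 + cos(pi * (lo - f_fold[edge])))
    edge <- f_fold > hi & f_fold < hi + 1
    s[edge] <- 0.5 * (1 + cos(pi * (f_fold[edge] - hi)))
    if (sum(s) > 0) {
      g2_osc <- g2_osc + s * (n * band_rms_uv[[b]]^2 / sum(s))
    }
  }
  # draw the complex white spectrum directly (background and the
  # channel-independent oscillation share are independent Gaussians, so
  # their power spectra add); the shared-source spectrum is added to
  # every channel before one inverse FFT yields the real segment
  g_ind <- sqrt((g2_pink + (1 - rho) * g2_osc) * n)
  g_shared <- sqrt(rho * g2_osc * n)
  w <- matrix(stats::rnorm(n * n_channels), n, n_channels) +
    1i * matrix(stats::rnorm(n * n_channels), n, n_channels)
  ws <- stats::rnorm(n) + 1i * stats::rnorm(n)
  x <- w * g_ind + (ws * g_shared)
  Re(stats::mvfft(x, inverse = TRUE)) / n
}

#' Simulate one EEG recording session
#'
#' Generates a complete marker-coded session for one subject: a 3 s
#' baseline, eighteen 60 s playbacks and 5 s gaps at the native rate, with
#' 32 channels in the native amplifier order. Each clip's spectrum is
#' drawn from the class band-power profile of its keyword's latent
#' valence/arousal (plus the configured group shift and per-subject
#' variability) on top of a 1/f background; baseline and gaps carry the
#' neutral profile. Deterministic given the config seed, subject id and
#' group.
#'
#' @param config A [sim_config()].
#' @param subject_id Subject identifier string.
#' @param group `"photograph"` or `"artwork"`.
#' @param clip_labels Data.frame of `n_clips` rows with columns `keyword`,
#'   `medium`, covering all nine keywords (default
#'   [default_clip_labels()]).
#' @return An `eeg_session`: list with `subject_id`, `group`,
#'   `sample_rate`, `channel_labels`, `data` (32 x T matrix, microvolts),
#'   `markers` (marker data.frame), `baseline_ms`, and the per-clip latent
#'   affect in `clip_info`.
#' @export
simulate_session <- function(config, subject_id, group,
                             clip_labels = default_clip_labels(config$keyword_table)) {
  stopifnot(inherits(config, "sim_config"))
  if (!group %in% c("photograph", "artwork")) {
    invalid_argument("group must be 'photograph' or 'artwork'")
  }
  if (nrow(clip_labels) != config$n_clips) {
    invalid_argument(sprintf("clip_labels must have %d rows, got %d",
                             config$n_clips, nrow(clip_labels)))
  }
  kt <- config$keyword_table
  if (!all(kt$keyword %in% clip_labels$keyword)) {
    invalid_argument("clip_labels must cover all nine keywords")
  }
  rate <- config$native_rate
  markers <- build_marker_sequence(config$n_clips, config$clip_ms,
                                   config$gap_ms, config$baseline_ms, rate)
  n_total <- ms_to_samples(config$baseline_ms +
                             config$n_clips * (config$clip_ms + config$gap_ms),
                           rate)
  # latent affect per clip: keyword coordinate + group shift + subject noise
  shift_v <- if (group == "artwork") config$valence_effect_size * config$response_sd else 0
  shift_a <- if (group == "artwork") config$arousal_effect_size * config$response_sd else 0
  idx <- match(clip_labels$keyword, kt$keyword)
  lat <- with_substream(config$seed, "latent", subject_id, expr = {
    data.frame(
      clip = seq_len(config$n_clips),
      keyword = clip_labels$keyword,
      medium = clip_labels$medium,
      valence = clamp(kt$valence[idx] + shift_v +
                        stats::rnorm(config$n_clips, 0, config$response_sd)),
      arousal = clamp(kt$arousal[idx] + shift_a +
                        stats::rnorm(config$n_clips, 0, config$response_sd)),
      stringsAsFactors = FALSE
    )
  })

  n_ch <- 32L
  data <- matrix(0, n_ch, n_total)
  neutral <- band_multipliers(0, 0, config$class_band_powers)
  fill_segment <- function(from, n_seg, mult, key) {
    amp <- config$band_amplitude_uv * sqrt(mult[names(config$band_amplitude_uv)])
    seg <- with_substream(config$seed, "segment", subject_id, key,
                          expr = gen_eeg_segment(n_seg, rate, n_ch,
                                                 as.list(amp), config$noise,
                                                 config$channel_correlation))
    data[, from:(from + n_seg - 1)] <<- t(seg)
  }
  b_n <- ms_to_samples(config$baseline_ms, rate)
  clip_n <- ms_to_samples(config$clip_ms, rate)
  gap_n <- ms_to_samples(config$gap_ms, rate)
  fill_segment(1L, b_n, neutral, "baseline")
  for (i in seq_len(config$n_clips)) {
    start <- markers$sample_index[markers$code == 2L * i] + 1L  # to 1-based
    mult <- band_multipliers(lat$valence[i], lat$arousal[i],
                             config$class_band_powers)
    fill_segment(start, clip_n, mult, paste0("clip", i))
    gap_start <- start + clip_n
    n_gap_here <- min(gap_n, n_total - gap_start + 1L)
    if (n_gap_here > 0) fill_segment(gap_start, n_gap_here, neutral,
                                     paste0("gap", i))
  }
  session <- structure(
    list(subject_id = subject_id, group = group, sample_rate = rate,
         channel_labels = native_channel_order(), data = data,
         markers = markers, baseline_ms = config$baseline_ms,
         clip_info = lat),
    class = "eeg_session"
  )
  validate_session(session)
  session
}

#' Validate an EEG session's structural invariants
#'
#' Checks the 32-channel shape, marker codes and bounds, and total
#' duration. Called by the constructors; exported for user-loaded data.
#'
#' @param session An `eeg_session`.
#' @return The session, invisibly; signals `invalid_argument` on violation.
#' @export
validate_session <- function(session) {
  d <- session$data
  if (nrow(d) != 32) invalid_argument("session must have exactly 32 channels")
  if (length(session$channel_labels) != 32 ||
      anyDuplicated(session$channel_labels)) {
    invalid_argument("session needs 32 distinct channel labels")
  }
  m <- session$markers
  if (any(m$sample_index < 0) || any(m$sample_index >= ncol(d))) {
    invalid_argument("marker sample_index out of recording bounds")
  }
  if (is.unsorted(m$sample_index[order(m$code)], strictly = FALSE)) {
    invalid_argument("marker sample indices must increase with code")
  }
  invisible(session)
}

#' @export
print.eeg_session <- function(x, ...) {
  cat(sprintf("<eeg_session> subject %s (%s): %d ch x %d samples @ %g Hz, %d markers\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data),
              x$sample_rate, nrow(x$markers)))
  invisible(x)
}

#' Construct a preprocessed trial
#'
#' @param subject_id Subject identifier.
#' @param data Channels x samples matrix (microvolts).
#' @param sample_rate Sampling rate in Hz (128 for DEAP-format trials).
#' @param keyword,medium Emotion keyword and medium tags (may be `NA` for
#'   label-only training trials).
#' @param valence_label,arousal_label Binary labels in `{+1, -1}` (or `NA`).
#' @return An `eeg_trial` object.
#' @export
new_trial <- function(subject_id, data, sample_rate = 128,
                      keyword = NA_character_, medium = NA_character_,
                      valence_label = NA_integer_, arousal_label = NA_integer_) {
  if (!is.matrix(data) || !all(is.finite(data))) {
    invalid_argument("trial data must be a finite numeric matrix")
  }
  structure(
    list(subject_id = subject_id, keyword = keyword, medium = medium,
         data = data, sample_rate = sample_rate,
         valence_label = valence_label, arousal_label = arousal_label),
    class = "eeg_trial"
  )
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf("<eeg_trial> subject %s [%s/%s]: %d x %d @ %g Hz\n",
              x$subject_id, x$keyword, x$medium, nrow(x$data), ncol(x$data),
              x$sample_rate))
  invisible(x)
}

#' Simulate DEAP-style labeled trials
#'
#' Generates 32 x 7680 trials at 128 Hz with binary valence/arousal labels,
#' emulating the schema of the DEAP benchmark used to train the
#' recognizer. Labels are balanced within each participant; the trial
#' spectrum follows the class band-power profile at the label extremes.
#'
#' @param config A [sim_config()].
#' @param participant_ids Character vector of participant ids.
#' @param trials_each Trials per participant (DEAP uses 40).
#' @return List of `eeg_trial` objects (channels already in DEAP order).
#' @export
simulate_deap_trials <- function(config, participant_ids, trials_each = 40L) {
  stopifnot(inherits(config, "sim_config"))
  if (trials_each < 1) invalid_argument("trials_each must be >= 1")
  n_samp <- 60 * 128
  out <- vector("list", length(participant_ids) * trials_each)
  j <- 0L
  for (pid in participant_ids) {
    labs <- with_substream(config$seed, "deap-labels", pid, expr = {
      v <- rep(c(1L, -1L), length.out = trials_each)
      a <- rep(c(1L, 1L, -1L, -1L), length.out = trials_each)
      cbind(sample(v), sample(a))
    })
    for (t in seq_len(trials_each)) {
      mult <- band_multipliers(labs[t, 1], labs[t, 2], config$class_band_powers)
      amp <- config$band_amplitude_uv * sqrt(mult[names(config$band_amplitude_uv)])
      seg <- with_substream(config$seed, "deap-trial", pid, t,
                            expr = gen_eeg_segment(n_samp, 128, 32,
                                                   as.list(amp), config$noise,
                                                   config$channel_correlation))
      j <- j + 1L
      out[[j]] <- new_trial(pid, t(seg), 128,
                            valence_label = labs[t, 1],
                            arousal_label = labs[t, 2])
    }
  }
  out
}

#' Simulate per-subject valence/arousal response tables
#'
#' Draws one valence and one arousal score per keyword for each subject in
#' the two media groups. Photograph-group scores are drawn around a
#' per-keyword baseline (0.3 x the keyword's coordinate) with standard
#' deviation `response_sd`; artwork-group scores are shifted by
#' `effect_size * response_sd` on the corresponding axis, so the
#' standardized group difference equals the configured Cohen's d. Scores
#' are clamped to `[-1, 1]` (the clamp sits more than 4 standard
#' deviations from every mean and is statistically negligible).
#'
#' @param config A [sim_config()].
#' @return Data.frame with one row per subject x keyword and columns
#'   `subject_id`, `group`, `keyword`, `valence`, `arousal`.
#' @export
simulate_response_tables <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  kt <- config$keyword_table
  rows <- vector("list", 2L * config$n_subjects_per_group)
  i <- 0L
  for (group in c("photograph", "artwork")) {
    shift_v <- if (group == "artwork") config$valence_effect_size * config$response_sd else 0
    shift_a <- if (group == "artwork") config$arousal_effect_size * config$response_sd else 0
    for (s in seq_len(config$n_subjects_per_group)) {
      sid <- sprintf("%s_%02d", substr(group, 1, 5), s)
      sc <- with_substream(config$seed, "response", group, s, expr = {
        data.frame(
          subject_id = sid, group = group, keyword = kt$keyword,
          valence = clamp(0.3 * kt$valence + shift_v +
                            stats::rnorm(nrow(kt), 0, config$response_sd)),
          arousal = clamp(0.3 * kt$arousal + shift_a +
                            stats::rnorm(nrow(kt), 0, config$response_sd)),
          stringsAsFactors = FALSE
        )
      })
      i <- i + 1L
      rows[[i]] <- sc
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
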