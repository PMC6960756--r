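# Zero-phase filtering: multiply the spectrum by the filter's squared
# magnitude response (the frequency-domain equivalent of forward-backward
# application), vectorized across channels with one FFT. Phase is exactly
# zero, so marker-aligned events are never shifted by group delay.
zero_phase_filter <- function(x, filt, rate) {
  s <- ncol(x)
  f_fold <- pmin((seq_len(s) - 1), s - (seq_len(s) - 1)) * rate / s
  w <- 2 * pi * f_fold / rate
  z <- exp(-1i * w)
  num <- 0 + 0i; den <- 0 + 0i; zp <- rep(1 + 0i, s)
  for (i in seq_along(filt$b)) {
    num <- num + filt$b[i] * zp
    den <- den + filt$a[i] * zp
    zp <- zp * z
  }
  h2 <- Mod(num / den)^2
  X <- stats::mvfft(t(x)) * h2
  t(Re(stats::mvfft(X, inverse = TRUE)) / s)
}

#' Downsample a multichannel signal
#'
#' Anti-aliased rate conversion: a zero-phase Butterworth low-pass
#' (order 8, cutoff at 80% of the output Nyquist, squared-magnitude
#' response applied in the frequency domain) followed by cubic-spline
#' resampling at the output
#' sample times. Content above the output Nyquist is attenuated by more
#' than 40 dB; a pure tone in the passband keeps its frequency and
#' amplitude.
#'
#' @param x Channels x samples numeric matrix (or a single-channel vector).
#' @param from_rate Input sampling rate in Hz.
#' @param to_rate Output sampling rate in Hz (default 128, the DEAP rate).
#' @return Matrix with the same number of channels and
#'   `floor(ncol(x) * to_rate / from_rate)` samples.
#' @export
downsample <- function(x, from_rate, to_rate = 128) {
  if (from_rate < to_rate) {
    invalid_argument("from_rate must be >= to_rate")
  }
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  if (from_rate == to_rate) return(if (vec) drop(x) else x)
  n_in <- ncol(x)
  n_out <- as.integer(floor(n_in * to_rate / from_rate))
  bf <- signal::butter(8, (0.8 * to_rate / 2) / (from_rate / 2), type = "low")
  xf <- zero_phase_filter(x, bf, from_rate)
  t_in <- (seq_len(n_in) - 1) / from_rate
  t_out <- (seq_len(n_out) - 1) / to_rate
  out <- matrix(0, nrow(x), n_out)
  for (c in seq_len(nrow(x))) {
    out[c, ] <- stats::spline(t_in, xf[c, ], xout = t_out,
                              method = "natural")$y
  }
  if (vec) drop(out) else out
}

# Downsample a whole session: data plus marker positions and rate.
#' Downsample an EEG session in place
#'
#' Applies [downsample()] to the session data and rescales the marker
#' sample indices to the new rate.
#'
#' @param session An `eeg_session`.
#' @param to_rate Target rate in Hz.
#' @return The downsampled `eeg_session`.
#' @export
downsample_session <- function(session, to_rate = 128) {
  if (session$sample_rate == to_rate) return(session)
  session$data <- downsample(session$data, session$sample_rate, to_rate)
  session$markers$sample_index <- pmin(
    as.integer(floor(session$markers$sample_index * to_rate / session$sample_rate)),
    ncol(session$data) - 1L
  )
  session$sample_rate <- to_rate
  session
}

#' Band-pass filter a multichannel signal
#'
#' Zero-phase 4th-order Butterworth band-pass (squared-magnitude response
#' applied in the frequency domain). With the
#' default 4-45 Hz band this is the standard pass band used to align
#' recordings with the DEAP preprocessing; zero-phase application means
#' marker-aligned events are not shifted by group delay. Stop-band
#' attenuation exceeds 20 dB one octave outside the band.
#'
#' @param x Channels x samples matrix (or vector).
#' @param rate Sampling rate in Hz.
#' @param low,high Band edges in Hz; must satisfy `0 < low < high <
#'   rate/2`.
#' @return Filtered signal, same shape as the input.
#' @export
bandpass <- function(x, rate, low = 4, high = 45) {
  if (low <= 0 || high <= low || high >= rate / 2) {
    invalid_argument("band must satisfy 0 < low < high < Nyquist")
  }
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  bf <- signal::butter(4, c(low, high) / (rate / 2), type = "pass")
  out <- zero_phase_filter(x, bf, rate)
  if (vec) drop(out) else out
}

#' Reorder the channels of a session
#'
#' Permutes the rows of the session data so row `i` carries the channel
#' named `target_order[i]`. Values are untouched. Used to bring native
#' amplifier recordings into the DEAP channel order.
#'
#' @param session An `eeg_session`.
#' @param target_order Character vector: a permutation of the session's
#'   channel labels (default [deap_channel_order()]).
#' @return The session with permuted rows and updated labels.
#' @export
reorder_channels <- function(session, target_order = deap_channel_order()) {
  cur <- session$channel_labels
  if (length(target_order) != length(cur) ||
      anyDuplicated(target_order) > 0 ||
      !setequal(target_order, cur)) {
    missing <- setdiff(target_order, cur)
    extra <- setdiff(cur, target_order)
    stop_eegaffect(
      "channel_mismatch",
      sprintf("target_order is not a permutation of the session channels (missing: %s; absent from target: %s)",
              paste(missing, collapse = ", "), paste(extra, collapse = ", "))
    )
  }
  perm <- match(target_order, cur)
  session$data <- session$data[perm, , drop = FALSE]
  session$channel_labels <- target_order
  session
}

# Check the marker table carries exactly codes 1 .. 2n+2, once each.
check_marker_protocol <- function(markers, n_clips) {
  expected <- seq_len(2L * n_clips + 2L)
  codes <- markers$code
  missing <- setdiff(expected, codes)
  dup <- unique(codes[duplicated(codes)])
  if (length(missing) > 0 || length(dup) > 0) {
    stop_eegaffect(
      "protocol_violation",
      sprintf("incomplete marker protocol (missing codes: %s; duplicated codes: %s)",
              paste(missing, collapse = ", "),
              paste(dup, collapse = ", ")),
      missing_codes = missing, duplicated_codes = dup
    )
  }
  invisible(TRUE)
}

#' Segment a session into labeled trials and a baseline
#'
#' Cuts the recording at the playback start markers: trial `n` spans the
#' 60 s from the sample of marker code `2n`; the baseline spans from code
#' 1 to the first playback. The session must carry the complete marker
#' protocol (codes `1 .. 2 * n_clips + 2`, each exactly once).
#'
#' @param session An `eeg_session` (at any rate; trial lengths follow the
#'   session's current rate).
#' @param clip_labels Data.frame with `n_clips` rows, columns `keyword`
#'   and `medium`, giving each playback's tag.
#' @param clip_ms,baseline_ms Playback and baseline durations (ms).
#' @return List with `trials` (list of `eeg_trial`) and `baseline`
#'   (channels x samples matrix).
#' @export
slice_trials <- function(session, clip_labels, clip_ms = 60000,
                         baseline_ms = 3000) {
  n_clips <- nrow(clip_labels)
  check_marker_protocol(session$markers, n_clips)
  rate <- session$sample_rate
  clip_n <- ms_to_samples(clip_ms, rate)
  m <- session$markers
  trials <- vector("list", n_clips)
  for (i in seq_len(n_clips)) {
    start <- m$sample_index[m$code == 2L * i] + 1L  # 0-based marker -> R index
    if (start + clip_n - 1L > ncol(session$data)) {
      stop_eegaffect("protocol_violation",
                     sprintf("trial %d extends past the end of the recording", i))
    }
    trials[[i]] <- new_trial(
      session$subject_id,
      session$data[, start:(start + clip_n - 1L), drop = FALSE],
      rate, keyword = clip_labels$keyword[i], medium = clip_labels$medium[i]
    )
  }
  b_start <- m$sample_index[m$code == 1L] + 1L
  b_n <- ms_to_samples(baseline_ms, rate)
  baseline <- session$data[, b_start:(b_start + b_n - 1L), drop = FALSE]
  list(trials = trials, baseline = baseline)
}

#' Remove the linear trend from each channel
#'
#' Subtracts the per-channel least-squares line (intercept + slope), so
#' every output channel has exactly zero mean and no linear drift.
#'
#' @param x An `eeg_trial` or a channels x samples matrix.
#' @return Object of the same type with detrended data.
#' @export
detrend <- function(x) {
  if (inherits(x, "eeg_trial")) {
    x$data <- detrend(x$data)
    return(x)
  }
  n <- ncol(x)
  tt <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, tt), t(x))
  t(fit$residuals)
}

#' Run the full preprocessing pipeline on a session
#'
#' Applies, in this fixed order: downsample to 128 Hz, band-pass
#' 4-45 Hz, reorder channels to the DEAP montage, segment into trials
#' plus baseline, and detrend each trial. The order is recorded in the
#' returned `stage_log`.
#'
#' @param session An `eeg_session` at its native rate.
#' @param clip_labels Data.frame of per-playback `keyword`/`medium` tags.
#' @param to_rate Target rate (Hz, default 128).
#' @param band Band-pass edges in Hz (default `c(4, 45)`).
#' @param target_order Target channel order (default
#'   [deap_channel_order()]).
#' @param subtract_baseline If `TRUE`, the per-channel mean of the 3 s
#'   baseline segment is subtracted from every trial before detrending
#'   (off by default; the recorded baseline is retained either way).
#' @param clip_ms,baseline_ms Segment durations (ms).
#' @return List with `trials` (18 detrended `eeg_trial`s, 32 x 7680 at
#'   128 Hz under the defaults), `baseline` (matrix) and `stage_log`
#'   (character vector of stages in execution order).
#' @export
preprocess_session <- function(session, clip_labels,
                               to_rate = 128, band = c(4, 45),
                               target_order = deap_channel_order(),
                               subtract_baseline = FALSE,
                               clip_ms = 60000, baseline_ms = 3000) {
  log <- character(0)
  session <- downsample_session(session, to_rate)
  log <- c(log, "downsample")
  session$data <- bandpass(session$data, session$sample_rate,
                           band[1], band[2])
  log <- c(log, "bandpass")
  session <- reorder_channels(session, target_order)
  log <- c(log, "reorder")
  sliced <- slice_trials(session, clip_labels, clip_ms, baseline_ms)
  log <- c(log, "slice")
  if (subtract_baseline) {
    bl_mean <- rowMeans(sliced$baseline)
    sliced$trials <- lapply(sliced$trials, function(tr) {
      tr$data <- tr$data - bl_mean
      tr
    })
  }
  sliced$trials <- lapply(sliced$trials, detrend)
  log <- c(log, "detrend")
  list(trials = sliced$trials, baseline = sliced$baseline, stage_log = log)
}
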