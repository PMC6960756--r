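#' Window extraction specification
#'
#' @param width Window width in time samples (32, fixed by the 32 x 32
#'   model input).
#' @param stride Offset between consecutive windows in time samples. The
#'   published per-trial window counts pin the useful range: stride 232
#'   gives 33 windows per 60 s trial and stride 96 gives 80 (the default).
#' @param layout `"channels_by_time"`: a window is the 32 channels by
#'   `width` consecutive time samples. `"single_channel_folded"` is also
#'   accepted (1024 consecutive samples of one channel folded 32 x 32);
#'   the channels-by-time layout is the default because it preserves the
#'   spatial montage.
#' @return A `window_spec` object.
#' @export
window_spec <- function(width = 32L, stride = 96L,
                        layout = c("channels_by_time", "single_channel_folded")) {
  layout <- match.arg(layout)
  if (stride < 1) invalid_argument("stride must be >= 1")
  if (width < 1) invalid_argument("width must be >= 1")
  structure(list(width = as.integer(width), stride = as.integer(stride),
                 layout = layout),
            class = "window_spec")
}

#' Number of windows per trial for a given stride
#'
#' Closed form `floor((n_samples - width) / stride) + 1`, the count of
#' window start offsets `0, stride, 2*stride, ...` that keep the window
#' inside the trial.
#'
#' @param stride Stride in samples.
#' @param n_samples Trial length (default 7680).
#' @param width Window width (default 32).
#' @return Integer window count.
#' @export
windows_per_trial <- function(stride, n_samples = 7680L, width = 32L) {
  if (stride < 1) invalid_argument("stride must be >= 1")
  as.integer(floor((n_samples - width) / stride) + 1L)
}

#' Extract 32 x 32 window samples from a trial
#'
#' Slides a `width`-sample window along the trial at the given stride.
#' Every window inherits the parent trial's labels and tags.
#'
#' @param trial An `eeg_trial` with a 32 x 7680 data matrix.
#' @param spec A [window_spec()].
#' @return A `window_set`: list with `x` (array `32 x 32 x n`) and `meta`
#'   (data.frame with `subject_id`, `keyword`, `medium`, `offset`,
#'   `valence_label`, `arousal_label`).
#' @export
extract_windows <- function(trial, spec = window_spec()) {
  stopifnot(inherits(trial, "eeg_trial"))
  d <- trial$data
  if (nrow(d) != 32) invalid_argument("trial must have 32 channels")
  n <- ncol(d)
  # span of one window along the time axis: `width` samples for the
  # channels-by-time layout, width^2 consecutive samples of one channel
  # for the folded layout
  span <- if (spec$layout == "channels_by_time") spec$width else spec$width^2
  if (span > n) invalid_argument("window span exceeds trial length")
  offsets <- seq.int(0L, n - span, by = spec$stride)
  xarr <- array(0, dim = c(spec$width, spec$width, length(offsets)))
  for (i in seq_along(offsets)) {
    if (spec$layout == "channels_by_time") {
      xarr[, , i] <- d[, (offsets[i] + 1L):(offsets[i] + spec$width)]
    } else {
      xarr[, , i] <- matrix(d[1L, (offsets[i] + 1L):(offsets[i] + span)],
                            spec$width, spec$width)
    }
  }
  meta <- data.frame(
    subject_id = trial$subject_id,
    keyword = trial$keyword,
    medium = trial$medium,
    offset = offsets,
    valence_label = trial$valence_label,
    arousal_label = trial$arousal_label,
    stringsAsFactors = FALSE
  )
  structure(list(x = xarr, meta = meta), class = "window_set")
}

#' Combine several window sets
#'
#' @param ... `window_set` objects (or a single list of them).
#' @return One `window_set` holding all windows.
#' @export
bind_window_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && !inherits(sets[[1]], "window_set")) sets <- sets[[1]]
  xs <- lapply(sets, `[[`, "x")
  n <- sum(vapply(xs, function(a) dim(a)[3], integer(1)))
  out <- array(0, dim = c(dim(xs[[1]])[1], dim(xs[[1]])[2], n))
  at <- 0L
  for (a in xs) {
    k <- dim(a)[3]
    out[, , (at + 1L):(at + k)] <- a
    at <- at + k
  }
  structure(list(x = out, meta = do.call(rbind, lapply(sets, `[[`, "meta"))),
            class = "window_set")
}

#' Assembled dataset size
#'
#' Total number of window samples contributed by a participant set:
#' `n_participants * trials_each * windows_per_trial`. With the 22/5/5
#' participant split, 40 trials each and 33-80 windows per trial this
#' reproduces the published dataset-size range (29,040-70,400 training
#' samples; 6,600-16,000 for validation and test).
#'
#' @param n_participants,trials_each,windows_per_trial Positive integers.
#' @return The product, as a double (sizes can exceed integer range).
#' @export
dataset_size <- function(n_participants, trials_each, windows_per_trial) {
  if (n_participants < 1 || trials_each < 1 || windows_per_trial < 1) {
    invalid_argument("all dataset-size factors must be positive")
  }
  as.numeric(n_participants) * trials_each * windows_per_trial
}

#' Participant split specification
#'
#' @param n_train,n_val,n_test Participants per split (defaults 22/5/5,
#'   the published DEAP split).
#' @param trials_per_participant Trials recorded per participant (40).
#' @param seed Integer seed for the random assignment.
#' @return A `split_spec` object.
#' @export
split_spec <- function(n_train = 22L, n_val = 5L, n_test = 5L,
                       trials_per_participant = 40L, seed = 1L) {
  structure(list(n_train = as.integer(n_train), n_val = as.integer(n_val),
                 n_test = as.integer(n_test),
                 trials_per_participant = as.integer(trials_per_participant),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Partition participants into train/validation/test sets
#'
#' Random, seeded, disjoint assignment. Splitting at the participant
#' level guarantees no window of one participant ever appears in two
#' splits.
#'
#' @param participant_ids Vector of distinct participant ids whose length
#'   must equal `n_train + n_val + n_test`.
#' @param spec A [split_spec()].
#' @return List with elements `train`, `validation`, `test`.
#' @export
split_participants <- function(participant_ids, spec = split_spec()) {
  total <- spec$n_train + spec$n_val + spec$n_test
  if (length(participant_ids) != total) {
    invalid_argument(sprintf("cohort size %d does not match split total %d",
                             length(participant_ids), total))
  }
  if (anyDuplicated(participant_ids)) {
    invalid_argument("participant ids must be distinct")
  }
  shuffled <- with_substream(spec$seed, "participant-split",
                             expr = sample(participant_ids))
  list(
    train = shuffled[seq_len(spec$n_train)],
    validation = shuffled[spec$n_train + seq_len(spec$n_val)],
    test = shuffled[spec$n_train + spec$n_val + seq_len(spec$n_test)]
  )
}
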