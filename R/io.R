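# Session, marker, response-table and window-set persistence.
#
# Sessions are stored as EDF (European Data Format: 256-byte global
# header, 256 bytes per signal, 16-bit little-endian samples in 1-second
# records) with the event markers in a sidecar CSV, since annotations are
# not part of plain EDF.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

#' Write a session to an EDF file with a marker sidecar CSV
#'
#' Signals are scaled to the 16-bit digital range against a symmetric
#' per-channel physical range, in 1-second data records. The subject id
#' and group are stored in the EDF patient field. Markers go to
#' `<path without .edf>_markers.csv` (columns `code`, `sample_index`,
#' `description`).
#'
#' @param session An `eeg_session` with an integer sample rate and a
#'   whole number of seconds of data.
#' @param path Output path (conventionally `.edf`).
#' @return The path, invisibly.
#' @export
write_session_edf <- function(session, path) {
  d <- session$data
  rate <- session$sample_rate
  if (rate != round(rate)) invalid_argument("EDF export needs an integer rate")
  n_rec <- ncol(d) %/% rate
  if (n_rec * rate != ncol(d)) {
    invalid_argument("EDF export needs a whole number of 1-second records")
  }
  ns <- nrow(d)
  # use the physical range exactly as it will be printed in the header
  # (6 significant digits), so read-back scaling is self-consistent
  phys_max <- as.numeric(sprintf("%.6g",
                                 pmax(apply(abs(d), 1, max), 1e-6) * 1.0001))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(paste(session$subject_id, session$group), 80),
    pad_field("eegaffect synthetic session", 80),
    pad_field("01.01.20", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field("1", 8), pad_field(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    list(session$channel_labels, 16),
    list(rep("AgAgCl electrode", ns), 80),
    list(rep("uV", ns), 8),
    list(sprintf("%.6g", -phys_max), 8),
    list(sprintf("%.6g", phys_max), 8),
    # symmetric digital range so gain = phys_max/32767 and zero offset
    list(rep("-32767", ns), 8),
    list(rep("32767", ns), 8),
    list(rep("", ns), 80),
    list(rep(rate, ns), 8),
    list(rep("", ns), 32)
  )
  for (f in fields) {
    writeChar(paste0(vapply(f[[1]], pad_field, "", width = f[[2]]),
                     collapse = ""), con, eos = NULL)
  }
  scale <- 32767 / phys_max
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * rate + 1):(r * rate)
    block <- round(d[, cols, drop = FALSE] * scale)
    block <- pmin(pmax(block, -32767), 32767)
    # records store each signal's samples contiguously
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  utils::write.csv(session$markers, marker_sidecar_path(path),
                   row.names = FALSE)
  invisible(path)
}

marker_sidecar_path <- function(path) {
  paste0(sub("\\.edf$", "", path), "_markers.csv")
}

#' Read a session written by [write_session_edf()]
#'
#' @param path Path to the EDF file; the marker sidecar is looked up next
#'   to it.
#' @return An `eeg_session`.
#' @export
read_session_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)
  patient <- trimws(rd(80))
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  rd(80 * ns); rd(8 * ns)
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(32 * ns)
  rate <- spr[1] / rec_dur
  d <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = sum(spr), size = 2,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1])  # one column per signal
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    d[, cols] <- t(block)
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  d <- d * gain + (phys_max - gain * dig_max)
  parts <- strsplit(patient, " ")[[1]]
  markers <- utils::read.csv(marker_sidecar_path(path),
                             stringsAsFactors = FALSE)
  structure(
    list(subject_id = parts[1],
         group = if (length(parts) > 1) parts[2] else NA_character_,
         sample_rate = rate, channel_labels = labels, data = d,
         markers = markers, baseline_ms = NA_real_, clip_info = NULL),
    class = "eeg_session"
  )
}

#' Write / read a response table
#'
#' The shared CSV schema: `subject_id`, `group`, `keyword`, `valence`,
#' `arousal`.
#'
#' @param responses Response-table data.frame.
#' @param path CSV path.
#' @return `write_response_table()` the path invisibly;
#'   `read_response_table()` the data.frame.
#' @export
write_response_table <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_response_table
#' @export
read_response_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Persist a window set as a flat binary container plus index CSV
#'
#' Window values go to `<stem>.bin` (doubles, column-major per window);
#' the metadata (subject, trial tags, offset, labels) and array shape go
#' to `<stem>_index.csv`.
#'
#' @param ws A `window_set`.
#' @param stem Path stem (no extension).
#' @return The stem, invisibly.
#' @export
write_window_set <- function(ws, stem) {
  con <- file(paste0(stem, ".bin"), "wb")
  writeBin(as.vector(ws$x), con, size = 8, endian = "little")
  close(con)
  meta <- ws$meta
  meta$.dim1 <- dim(ws$x)[1]
  meta$.dim2 <- dim(ws$x)[2]
  utils::write.csv(meta, paste0(stem, "_index.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_window_set
#' @export
read_window_set <- function(stem) {
  meta <- utils::read.csv(paste0(stem, "_index.csv"),
                          stringsAsFactors = FALSE)
  d1 <- meta$.dim1[1]; d2 <- meta$.dim2[1]
  n <- nrow(meta)
  con <- file(paste0(stem, ".bin"), "rb")
  vals <- readBin(con, numeric(), n = d1 * d2 * n, size = 8,
                  endian = "little")
  close(con)
  meta$.dim1 <- NULL
  meta$.dim2 <- NULL
  structure(list(x = array(vals, dim = c(d1, d2, n)), meta = meta),
            class = "window_set")
}

#' Write / read preprocessed trials as a CSV directory
#'
#' Each trial's channels x samples matrix goes to `trial_<n>.csv`; the
#' metadata (subject, keyword, medium, rate, labels) goes to
#' `trials_index.csv` in the same directory.
#'
#' @param trials List of `eeg_trial` objects.
#' @param dir Output directory (created if needed).
#' @return `write_trials()` the directory invisibly; `read_trials()` the
#'   list of trials.
#' @export
write_trials <- function(trials, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- do.call(rbind, lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    utils::write.table(tr$data,
                       file.path(dir, sprintf("trial_%02d.csv", i)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    data.frame(file = sprintf("trial_%02d.csv", i),
               subject_id = tr$subject_id, keyword = tr$keyword,
               medium = tr$medium, sample_rate = tr$sample_rate,
               valence_label = tr$valence_label,
               arousal_label = tr$arousal_label,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(meta, file.path(dir, "trials_index.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_trials
#' @export
read_trials <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "trials_index.csv"),
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    d <- as.matrix(utils::read.csv(file.path(dir, meta$file[i]),
                                   header = FALSE))
    dimnames(d) <- NULL
    new_trial(meta$subject_id[i], d, meta$sample_rate[i],
              keyword = meta$keyword[i], medium = meta$medium[i],
              valence_label = meta$valence_label[i],
              arousal_label = meta$arousal_label[i])
  })
}
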