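# End-to-end orchestration: config validation, the simulate -> preprocess
# -> window -> train -> predict -> analyze chain, and the reproducibility
# manifest.

default_run_config <- function() {
  list(
    seed = 1L,
    output_dir = "eegaffect_run",
    log_level = "info",
    save_sessions = FALSE,
    simulation = list(
      n_subjects_per_group = 20L,
      native_rate = 500,
      valence_effect_size = 0,
      arousal_effect_size = 0,
      response_sd = 0.15
    ),
    window = list(stride = 96L, layout = "channels_by_time"),
    train = list(
      k = 5L, learning_rate = 1e-4, lr_decay_factor = 0.1,
      weight_decay = 0.5, weight_decay_mode = "off",
      batch_size = 100L, max_epochs = 30L, patience = 3L,
      n_train_participants = 22L, n_val_participants = 5L,
      trials_each = 40L, n_kernels = 24L, kernel_len = 16L
    ),
    test = list(var_equal = FALSE, adjust = "none")
  )
}

merge_config <- function(defaults, user, path = character(0)) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      stop_eegaffect("config_error", sprintf("unknown config key: %s", full))
    }
    if (is.list(defaults[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]])) {
        stop_eegaffect("config_error",
                       sprintf("config key %s must be a mapping", full))
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate a raw run configuration
#'
#' Accepts YAML text, a YAML/JSON file path, or a list; fills defaults,
#' rejects unknown keys with their dotted path, and validates stage
#' parameters against their modules' constructors.
#'
#' @param raw YAML text, a file path, a list, or `NULL`/empty for
#'   all-defaults.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(raw = NULL) {
  user <- if (is.null(raw)) {
    list()
  } else if (is.list(raw)) {
    raw
  } else if (length(raw) == 1 && file.exists(raw)) {
    yaml::read_yaml(raw)
  } else {
    yaml::yaml.load(paste(raw, collapse = "\n"))
  }
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_run_config(), user)
  if (cfg$window$stride < 1) {
    stop_eegaffect("config_error", "window.stride must be >= 1")
  }
  if (!cfg$window$layout %in% c("channels_by_time", "single_channel_folded")) {
    stop_eegaffect("config_error", "window.layout is invalid")
  }
  if (cfg$train$k < 1) stop_eegaffect("config_error", "train.k must be >= 1")
  if (cfg$simulation$n_subjects_per_group < 2) {
    stop_eegaffect("config_error",
                   "simulation.n_subjects_per_group must be >= 2")
  }
  structure(cfg, class = "run_config")
}

pipeline_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(format(Sys.time(), "%H:%M:%S "), sprintf(...))
}

#' Simulate a cohort and score every subject's clips
#'
#' For each subject of both media groups: simulate a session, run the
#' preprocessing pipeline, window each trial and score it with the
#' trained recognizer. Sessions are processed one at a time so memory
#' stays flat.
#'
#' @param model A trained `recognizer`.
#' @param scfg A [sim_config()] describing the cohort.
#' @param wspec A [window_spec()].
#' @param session_sink Optional function called with each simulated
#'   session (used by [run_pipeline()] to write EDF files).
#' @return Trial-score data.frame (`subject_id`, `group`, `medium`,
#'   `keyword`, `valence`, `arousal`), one row per subject x clip.
#' @export
score_cohort <- function(model, scfg, wspec = window_spec(),
                         session_sink = NULL) {
  clip_labels <- default_clip_labels(scfg$keyword_table)
  rows <- list()
  for (group in c("photograph", "artwork")) {
    for (s in seq_len(scfg$n_subjects_per_group)) {
      sid <- sprintf("%s_%02d", substr(group, 1, 5), s)
      session <- simulate_session(scfg, sid, group, clip_labels)
      if (!is.null(session_sink)) session_sink(session)
      prep <- preprocess_session(session, clip_labels,
                                 clip_ms = scfg$clip_ms,
                                 baseline_ms = scfg$baseline_ms)
      for (tr in prep$trials) {
        ws <- extract_windows(tr, wspec)
        sc <- score_trial(model, ws)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, group = group, medium = tr$medium,
          keyword = tr$keyword, valence = sc$valence, arousal = sc$arousal,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Build and train a recognizer on simulated DEAP-style trials.
train_on_synthetic_deap <- function(scfg, tcfg, arch, wspec,
                                    n_train, n_val, trials_each) {
  ids <- sprintf("deap_%02d", seq_len(n_train + n_val))
  train_ids <- ids[seq_len(n_train)]
  val_ids <- ids[n_train + seq_len(n_val)]
  to_ws <- function(pids) {
    trials <- simulate_deap_trials(scfg, pids, trials_each)
    bind_window_sets(lapply(trials, extract_windows, spec = wspec))
  }
  model <- build_columns(tcfg, arch)
  train_recognizer(model, to_ws(train_ids), to_ws(val_ids))
}

#' Run the full pipeline end to end
#'
#' Executes simulate -> preprocess -> window -> train -> predict ->
#' analyze under one root seed and writes all artifacts plus a manifest
#' (config, seed, package version, output checksums) to the output
#' directory. Re-running with the same config reproduces identical
#' checksums.
#'
#' @param config A `run_config` from [validate_config()] (or anything
#'   that function accepts).
#' @return Invisibly, a list with `responses`, `report`, `model`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- sim_config(
    seed = cfg$seed,
    n_subjects_per_group = cfg$simulation$n_subjects_per_group,
    native_rate = cfg$simulation$native_rate,
    valence_effect_size = cfg$simulation$valence_effect_size,
    arousal_effect_size = cfg$simulation$arousal_effect_size,
    response_sd = cfg$simulation$response_sd
  )
  tcfg <- train_config(
    k = cfg$train$k, learning_rate = cfg$train$learning_rate,
    lr_decay_factor = cfg$train$lr_decay_factor,
    weight_decay = cfg$train$weight_decay,
    weight_decay_mode = cfg$train$weight_decay_mode,
    batch_size = cfg$train$batch_size, max_epochs = cfg$train$max_epochs,
    patience = cfg$train$patience, seed = cfg$seed
  )
  arch <- column_arch(n_kernels = cfg$train$n_kernels,
                      kernel_len = cfg$train$kernel_len)
  wspec <- window_spec(stride = cfg$window$stride,
                       layout = cfg$window$layout)

  pipeline_log(cfg, "training recognizer (k = %d) on synthetic DEAP-style trials",
               tcfg$k)
  model <- train_on_synthetic_deap(scfg, tcfg, arch, wspec,
                                   cfg$train$n_train_participants,
                                   cfg$train$n_val_participants,
                                   cfg$train$trials_each)
  utils::write.csv(model$history,
                   file.path(cfg$output_dir, "training_history.csv"),
                   row.names = FALSE)

  pipeline_log(cfg, "simulating and scoring %d subjects per group",
               scfg$n_subjects_per_group)
  sink_fun <- if (isTRUE(cfg$save_sessions)) {
    function(s) write_session_edf(
      s, file.path(cfg$output_dir, paste0(s$subject_id, ".edf")))
  } else NULL
  trial_scores <- score_cohort(model, scfg, wspec, sink_fun)
  utils::write.csv(trial_scores,
                   file.path(cfg$output_dir, "trial_scores.csv"),
                   row.names = FALSE)

  responses <- assemble_responses(trial_scores)
  write_response_table(responses, file.path(cfg$output_dir, "responses.csv"))

  pipeline_log(cfg, "comparing groups")
  report <- compare_groups(responses, var_equal = cfg$test$var_equal,
                           adjust = cfg$test$adjust)
  utils::write.csv(report, file.path(cfg$output_dir, "report.csv"),
                   row.names = FALSE)
  summary_path <- file.path(cfg$output_dir, "report_summary.txt")
  writeLines(utils::capture.output(print(report)), summary_path)

  manifest <- build_manifest(cfg, cfg$output_dir)
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(responses = responses, report = report, model = model,
                 manifest = manifest))
}

#' Desk-scale end-to-end recovery of a valence-only group effect
#'
#' Trains one recognizer on synthetic DEAP-style trials, then repeatedly
#' simulates fresh photograph/artwork cohorts in which only valence is
#' shifted, runs each cohort through the full preprocess-window-predict-
#' analyze chain, and asks how many of the nine keywords show a smaller
#' valence than arousal p-value on the per-keyword median over the
#' replicate cohorts. The defaults are the package's desk-scale
#' conditions (see the methods vignette): 2 recognizing columns, 4
#' subjects per group, a valence shift of d = 2 sized for that cohort,
#' and 20 replicate cohorts at 128 Hz native rate.
#'
#' @param seed Root seed.
#' @param n_seeds Number of replicate cohorts.
#' @param n_subjects_per_group Subjects per media group in each cohort.
#' @param valence_effect_size Injected standardized valence shift.
#' @param k Recognizer columns.
#' @return List with `median_p` (2 x 9 matrix of per-keyword median
#'   p-values), `n_valence_below` (count of keywords whose median valence
#'   p is below the median arousal p) and `per_seed_counts`.
#' @export
endtoend_recovery <- function(seed = 1L, n_seeds = 20L,
                              n_subjects_per_group = 4L,
                              valence_effect_size = 2,
                              k = 2L) {
  base <- sim_config(seed = substream_seed(seed, "e2e-train"),
                     native_rate = 128,
                     n_subjects_per_group = n_subjects_per_group,
                     valence_effect_size = valence_effect_size)
  tcfg <- train_config(k = k, learning_rate = 0.3, max_epochs = 10,
                       seed = substream_seed(seed, "e2e-model"))
  model <- train_on_synthetic_deap(base, tcfg, column_arch(),
                                   window_spec(stride = 232),
                                   n_train = 4, n_val = 2, trials_each = 6)
  wscore <- window_spec(stride = 96)
  pv <- matrix(NA_real_, n_seeds, 9)
  pa <- matrix(NA_real_, n_seeds, 9)
  counts <- integer(n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- base
    cfg$seed <- substream_seed(seed, "e2e-cohort", i)
    rep <- compare_groups(assemble_responses(score_cohort(model, cfg, wscore)))
    m <- report_matrix(rep)
    if (i == 1) colnames(pv) <- colnames(pa) <- colnames(m)
    pv[i, ] <- m["valence", ]
    pa[i, ] <- m["arousal", ]
    counts[i] <- sum(m["valence", ] < m["arousal", ])
  }
  med <- rbind(valence = apply(pv, 2, stats::median),
               arousal = apply(pa, 2, stats::median))
  list(median_p = med,
       n_valence_below = sum(med["valence", ] < med["arousal", ]),
       per_seed_counts = counts)
}

build_manifest <- function(cfg, out_dir) {
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  sums <- tools::md5sum(file.path(out_dir, files))
  names(sums) <- files
  canonical <- unclass(cfg)
  canonical$output_dir <- NULL  # path is location, not content
  list(
    package = "eegaffect",
    version = as.character(utils::packageVersion("eegaffect")),
    seed = cfg$seed,
    stages = c("simulate", "preprocess", "window", "train", "predict",
               "analyze"),
    config = canonical,
    checksums = as.list(sums)
  )
}
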