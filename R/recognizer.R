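#' Training configuration for the multi-column recognizer
#'
#' Holds the published training schedule: k = 5 recognizing columns,
#' learning rate 1e-4 decreased tenfold when the validation error stops
#' decreasing, batch size 100. The published "weight decay 0.5" is
#' ambiguous (0.5 is implausibly large for an L2 coefficient and may
#' denote a dropout rate or a decay schedule), so the coefficient is
#' exposed under three interpretations and regularization defaults off.
#'
#' @param k Number of recognizing columns (default 5).
#' @param learning_rate Initial SGD learning rate (default 1e-4).
#' @param lr_decay_factor Multiplier applied on a validation plateau
#'   (default 0.1).
#' @param weight_decay Regularization coefficient (default 0.5, the
#'   published value, but inactive under the default mode).
#' @param weight_decay_mode `"off"` (default), `"l2"` (coefficient used
#'   as an L2 penalty; a warning is issued for values > 0.1, which are
#'   implausibly large), or `"dropout"` (coefficient used as a feature
#'   dropout rate during training).
#' @param batch_size Minibatch size (default 100).
#' @param max_epochs Epoch cap (default 30).
#' @param patience Epochs without validation improvement before the
#'   learning rate is decayed (default 3); training stops after the
#'   learning rate has been decayed twice without further improvement.
#' @param seed Integer seed; column initialisation and batch shuffling
#'   derive substreams from it.
#' @return A `train_config` object.
#' @export
train_config <- function(k = 5L, learning_rate = 1e-4,
                         lr_decay_factor = 0.1, weight_decay = 0.5,
                         weight_decay_mode = c("off", "l2", "dropout"),
                         batch_size = 100L, max_epochs = 30L,
                         patience = 3L, seed = 1L) {
  weight_decay_mode <- match.arg(weight_decay_mode)
  if (k < 1) stop_eegaffect("config_error", "k must be >= 1")
  if (batch_size < 1) stop_eegaffect("config_error", "batch_size must be >= 1")
  if (learning_rate <= 0) stop_eegaffect("config_error", "learning_rate must be > 0")
  if (weight_decay_mode == "l2" && weight_decay > 0.1) {
    warning("weight_decay > 0.1 is implausibly large for an L2 coefficient; ",
            "consider weight_decay_mode = 'dropout'")
  }
  structure(list(k = as.integer(k), learning_rate = learning_rate,
                 lr_decay_factor = lr_decay_factor,
                 weight_decay = weight_decay,
                 weight_decay_mode = weight_decay_mode,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

#' Column architecture hyperparameters
#'
#' Each recognizing column is a small convolutional classifier: a bank of
#' randomly drawn band-limited temporal kernels (Hann-windowed sinusoids
#' with per-column random center frequencies and phases) whose rectified
#' energies, pooled over channels and time, feed a logistic readout. The
#' column honors the fixed contract: a 32 x 32 input maps to one class
#' probability.
#'
#' @param n_kernels Kernels per column (default 24).
#' @param kernel_len Kernel length in time samples (default 16, i.e.
#'   125 ms at 128 Hz).
#' @param freq_range Range (Hz) the random center frequencies are drawn
#'   from (default 3-45 Hz, spanning the analysis band).
#' @param sample_rate Rate the windows are sampled at (128 Hz).
#' @return A `column_arch` object.
#' @export
column_arch <- function(n_kernels = 24L, kernel_len = 16L,
                        freq_range = c(3, 45), sample_rate = 128) {
  if (n_kernels < 1 || kernel_len < 2) {
    stop_eegaffect("config_error", "need n_kernels >= 1 and kernel_len >= 2")
  }
  structure(list(n_kernels = as.integer(n_kernels),
                 kernel_len = as.integer(kernel_len),
                 freq_range = freq_range, sample_rate = sample_rate),
            class = "column_arch")
}

# Draw one column's random filterbank (kernel_len x n_kernels matrix).
make_column_kernels <- function(arch, seed, key) {
  with_substream(seed, "column-kernels", key, expr = {
    tt <- seq_len(arch$kernel_len) - 1
    freqs <- stats::runif(arch$n_kernels, arch$freq_range[1], arch$freq_range[2])
    phases <- stats::runif(arch$n_kernels, 0, 2 * pi)
    hann <- 0.5 * (1 - cos(2 * pi * (tt + 0.5) / arch$kernel_len))
    k <- vapply(seq_len(arch$n_kernels), function(j) {
      v <- hann * sin(2 * pi * freqs[j] * tt / arch$sample_rate + phases[j])
      v / sqrt(sum(v^2))
    }, numeric(arch$kernel_len))
    k
  })
}

#' Build an untrained multi-column recognizer
#'
#' Creates two independent model instances (one per affect axis), each
#' with `k` columns whose filterbanks are drawn from distinct seed
#' substreams, so the columns process the input independently.
#'
#' @param config A [train_config()].
#' @param arch A [column_arch()].
#' @return A `recognizer` object.
#' @export
build_columns <- function(config = train_config(), arch = column_arch()) {
  stopifnot(inherits(config, "train_config"), inherits(arch, "column_arch"))
  axes <- list()
  for (axis in c("valence", "arousal")) {
    axes[[axis]] <- lapply(seq_len(config$k), function(i) {
      list(kernels = make_column_kernels(arch, config$seed,
                                         paste(axis, i, sep = "-")),
           readout = NULL)
    })
  }
  structure(list(axes = axes, config = config, arch = arch,
                 history = NULL),
            class = "recognizer")
}

#' @export
print.recognizer <- function(x, ...) {
  trained <- !is.null(x$axes$valence[[1]]$readout)
  cat(sprintf("<recognizer> k = %d columns per axis, %d kernels x %d taps (%s)\n",
              x$config$k, x$arch$n_kernels, x$arch$kernel_len,
              if (trained) "trained" else "untrained"))
  invisible(x)
}

# Precomputed embedding index: rows of the (32*out_len) x L patch matrix
# address window elements in column-major order.
embed_index <- function(width, L) {
  out_len <- width - L + 1L
  idx <- matrix(0L, 32L * out_len, L)
  r <- 0L
  for (t in seq_len(out_len)) {
    for (c in 1:32) {
      r <- r + 1L
      idx[r, ] <- c + 32L * (t + seq_len(L) - 2L)
    }
  }
  idx
}

# Per-column log-energy features for every window in the array.
# Returns a list (one per kernel bank) of n x n_kernels matrices.
column_features <- function(xarr, kernel_banks) {
  width <- dim(xarr)[2]
  L <- nrow(kernel_banks[[1]])
  idx <- embed_index(width, L)
  n <- dim(xarr)[3]
  feats <- lapply(kernel_banks,
                  function(k) matrix(0, n, ncol(k)))
  for (w in seq_len(n)) {
    xv <- as.vector(xarr[, , w])
    E <- matrix(xv[idx], nrow(idx), L)
    for (b in seq_along(kernel_banks)) {
      A <- E %*% kernel_banks[[b]]
      feats[[b]][w, ] <- log(colMeans(A * A) + 1e-12)
    }
  }
  feats
}

# Minibatch SGD for a logistic readout with plateau-triggered lr decay.
# X, Xv are standardized feature matrices; y, yv in {0, 1}.
sgd_logistic <- function(X, y, Xv, yv, config, seed_key) {
  n <- nrow(X); p <- ncol(X)
  w <- numeric(p); b <- 0
  lr <- config$learning_rate
  best_val <- Inf; stall <- 0L; decays <- 0L
  hist <- list()
  wd <- if (config$weight_decay_mode == "l2") config$weight_decay else 0
  drop_rate <- if (config$weight_decay_mode == "dropout") config$weight_decay else 0
  for (epoch in seq_len(config$max_epochs)) {
    perm <- with_substream(config$seed, "shuffle", seed_key, epoch,
                           expr = sample.int(n))
    for (start in seq.int(1L, n, by = config$batch_size)) {
      rows <- perm[start:min(start + config$batch_size - 1L, n)]
      Xb <- X[rows, , drop = FALSE]
      if (drop_rate > 0) {
        mask <- with_substream(config$seed, "dropout", seed_key, epoch, start,
                               expr = stats::rbinom(p, 1, 1 - drop_rate))
        Xb <- sweep(Xb, 2, mask / max(1 - drop_rate, 1e-8), `*`)
      }
      z <- drop(Xb %*% w) + b
      pr <- 1 / (1 + exp(-z))
      err <- pr - y[rows]
      w <- w - lr * (drop(crossprod(Xb, err)) / length(rows) + wd * w)
      b <- b - lr * mean(err)
    }
    pred_err <- function(Xe, ye) {
      mean((drop(Xe %*% w) + b > 0) != (ye > 0.5))
    }
    tr_err <- pred_err(X, y)
    val_err <- pred_err(Xv, yv)
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                train_error = tr_err, val_error = val_err)
    if (val_err < best_val - 1e-9) {
      best_val <- val_err; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) {
        lr <- lr * config$lr_decay_factor
        decays <- decays + 1L
        stall <- 0L
        if (decays > 2L) break
      }
    }
  }
  list(w = w, b = b, history = do.call(rbind, hist))
}

#' Train the recognizer
#'
#' Trains every column's readout on the training windows, monitoring the
#' validation windows: the learning rate is multiplied by
#' `lr_decay_factor` whenever the validation error has not decreased for
#' `patience` consecutive epochs, and training stops at `max_epochs` or
#' after repeated decays bring no improvement. Training and validation
#' windows must come from disjoint participants.
#'
#' @param model A `recognizer` from [build_columns()].
#' @param train_ws,val_ws `window_set`s with `valence_label` /
#'   `arousal_label` metadata in `{+1, -1}`.
#' @return The trained `recognizer`; `$history` holds the per-epoch,
#'   per-column train/validation error.
#' @export
train_recognizer <- function(model, train_ws, val_ws) {
  stopifnot(inherits(model, "recognizer"))
  if (dim(train_ws$x)[3] == 0 || dim(val_ws$x)[3] == 0) {
    invalid_argument("training and validation sets must be non-empty")
  }
  shared <- intersect(unique(train_ws$meta$subject_id),
                      unique(val_ws$meta$subject_id))
  if (length(shared) > 0) {
    invalid_argument(sprintf("train/validation participants overlap: %s",
                             paste(shared, collapse = ", ")))
  }
  config <- model$config
  hist <- list()
  for (axis in names(model$axes)) {
    lab_col <- paste0(axis, "_label")
    y <- as.integer(train_ws$meta[[lab_col]] > 0)
    yv <- as.integer(val_ws$meta[[lab_col]] > 0)
    banks <- lapply(model$axes[[axis]], `[[`, "kernels")
    f_tr <- column_features(train_ws$x, banks)
    f_va <- column_features(val_ws$x, banks)
    for (i in seq_len(config$k)) {
      mu <- colMeans(f_tr[[i]])
      sdv <- pmax(apply(f_tr[[i]], 2, stats::sd), 1e-8)
      Xs <- sweep(sweep(f_tr[[i]], 2, mu), 2, sdv, `/`)
      Xvs <- sweep(sweep(f_va[[i]], 2, mu), 2, sdv, `/`)
      fit <- sgd_logistic(Xs, y, Xvs, yv, config, paste(axis, i, sep = "-"))
      model$axes[[axis]][[i]]$readout <-
        list(w = fit$w, b = fit$b, mu = mu, sd = sdv)
      h <- fit$history
      h$axis <- axis
      h$column <- i
      hist[[paste(axis, i)]] <- h
    }
  }
  model$history <- do.call(rbind, c(hist, list(make.row.names = FALSE)))
  model
}

# Column probabilities for every window: n x k matrix per axis.
column_probs <- function(model, xarr, axis) {
  banks <- lapply(model$axes[[axis]], `[[`, "kernels")
  feats <- column_features(xarr, banks)
  k <- model$config$k
  out <- matrix(0, dim(xarr)[3], k)
  for (i in seq_len(k)) {
    r <- model$axes[[axis]][[i]]$readout
    if (is.null(r)) stop_eegaffect("config_error", "recognizer is not trained")
    Xs <- sweep(sweep(feats[[i]], 2, r$mu), 2, r$sd, `/`)
    out[, i] <- 1 / (1 + exp(-(drop(Xs %*% r$w) + r$b)))
  }
  out
}

#' Fuse column decisions by probability-weighted vote
#'
#' Implements the weighted-average decision rule
#' `v_final = sum(w_i v_i) / sum(w_i)` over the k column decisions, where
#' `v_i` is the column's binary vote and `w_i` the predicted probability
#' of the voted class. Ties at exactly zero classify as +1 (documented
#' convention).
#'
#' @param decisions Data.frame (or list coercible to one) with columns
#'   `v` (votes in `{+1, -1}`) and `w` (probabilities in `[0, 1]`).
#' @return A `fused_decision`: list with `value` in `[-1, 1]` and `class`
#'   in `{+1, -1}`.
#' @export
#' @examples
#' fuse(data.frame(v = c(1, 1, 1, -1, -1), w = rep(0.8, 5)))$value  # 0.2
fuse <- function(decisions) {
  d <- as.data.frame(decisions)
  if (nrow(d) < 1) invalid_argument("need at least one column decision")
  if (!all(d$v %in% c(-1, 1))) invalid_argument("votes must be +1 or -1")
  if (any(d$w < 0 | d$w > 1)) invalid_argument("weights must lie in [0, 1]")
  sw <- sum(d$w)
  if (sw <= 0) {
    stop_eegaffect("degenerate_fusion", "all column weights are zero")
  }
  value <- sum(d$w * d$v) / sw
  structure(list(value = value, class = if (value >= 0) 1L else -1L),
            class = "fused_decision")
}

#' Per-window prediction
#'
#' Runs one 32 x 32 window through every column of both axis models and
#' fuses the column decisions.
#'
#' @param model A trained `recognizer`.
#' @param window A 32 x 32 numeric matrix.
#' @return List with one element per axis, each holding `columns`
#'   (data.frame of per-column `v`, `w`) and `fused` (a
#'   `fused_decision`).
#' @export
predict_window <- function(model, window) {
  if (!is.matrix(window) || !all(dim(window) == c(32, 32))) {
    stop_eegaffect("shape_error", "window must be a 32 x 32 matrix")
  }
  xarr <- array(window, dim = c(32, 32, 1))
  out <- list()
  for (axis in names(model$axes)) {
    p <- column_probs(model, xarr, axis)[1, ]
    v <- ifelse(p >= 0.5, 1L, -1L)
    w <- ifelse(v > 0, p, 1 - p)
    cols <- data.frame(v = v, w = w)
    out[[axis]] <- list(columns = cols, fused = fuse(cols))
  }
  out
}

# Fused values for every window in an array, one numeric vector per axis.
fused_values <- function(model, xarr) {
  sapply(names(model$axes), function(axis) {
    p <- column_probs(model, xarr, axis)
    v <- ifelse(p >= 0.5, 1, -1)
    w <- ifelse(v > 0, p, 1 - p)
    rowSums(w * v) / pmax(rowSums(w), 1e-12)
  }, simplify = FALSE)
}

#' Fused decision values for a whole window set
#'
#' Vectorized prediction: every window is run through all columns and
#' fused, per axis.
#'
#' @param model A trained `recognizer`.
#' @param ws A `window_set`.
#' @return List with numeric vectors `valence` and `arousal` of fused
#'   values in `[-1, 1]`, one per window.
#' @export
score_windows <- function(model, ws) {
  fused_values(model, ws$x)
}

#' Score a trial on both affect axes
#'
#' The per-axis trial score is the arithmetic mean of the fused decision
#' values over the trial's windows.
#'
#' @param model A trained `recognizer`.
#' @param trial_windows A `window_set` whose windows all come from one
#'   trial.
#' @return An `affect_score`: list with `valence` and `arousal` in
#'   `[-1, 1]`.
#' @export
score_trial <- function(model, trial_windows) {
  n <- dim(trial_windows$x)[3]
  if (n < 1) invalid_argument("trial has no windows")
  fv <- fused_values(model, trial_windows$x)
  structure(list(valence = mean(fv$valence), arousal = mean(fv$arousal)),
            class = "affect_score")
}

#' @export
print.affect_score <- function(x, ...) {
  cat(sprintf("<affect_score> valence %.3f, arousal %.3f\n",
              x$valence, x$arousal))
  invisible(x)
}
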