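#' Two-sample t-test between the media groups for one keyword
#'
#' Two-sided two-sample t-test of the per-subject scores, Welch
#' (unequal-variance) form by default with a Student option.
#'
#' @param photo_scores,artwork_scores Numeric vectors of per-subject
#'   scores, at least two finite values each.
#' @param var_equal If `TRUE` use the pooled-variance Student form.
#' @return List with `t_statistic`, `p_value`, `df`, and the two group
#'   means.
#' @export
keyword_ttest <- function(photo_scores, artwork_scores, var_equal = FALSE) {
  if (length(photo_scores) < 2 || length(artwork_scores) < 2) {
    invalid_argument("each group needs at least two observations")
  }
  if (!all(is.finite(photo_scores)) || !all(is.finite(artwork_scores))) {
    invalid_argument("scores must be finite")
  }
  if (stats::var(photo_scores) == 0 && stats::var(artwork_scores) == 0) {
    stop_eegaffect("degenerate_groups",
                   "both groups have zero variance; the t statistic is undefined")
  }
  tt <- stats::t.test(photo_scores, artwork_scores, var.equal = var_equal)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter),
       mean_photograph = mean(photo_scores),
       mean_artwork = mean(artwork_scores))
}

#' Classify a p-value into a significance tier
#'
#' Strict thresholds: `"p<0.01"` if p < 0.01, else `"p<0.05"` if
#' p < 0.05, else `"ns"`. Vectorized.
#'
#' @param p_value Numeric p-value(s) in `(0, 1]`.
#' @return Character vector of tiers.
#' @export
#' @examples
#' significance_tier(c(6.88e-8, 0.102, 0.05))
significance_tier <- function(p_value) {
  if (any(!is.finite(p_value)) || any(p_value <= 0) || any(p_value > 1)) {
    invalid_argument("p-values must lie in (0, 1]")
  }
  ifelse(p_value < 0.01, "p<0.01", ifelse(p_value < 0.05, "p<0.05", "ns"))
}

#' Compare the photograph and artwork groups keyword by keyword
#'
#' Runs the per-keyword, per-axis two-sample t-test on a response table
#' and tiers each p-value, producing the full 9-keyword x 2-axis
#' comparison grid.
#'
#' @param responses Response table (the shared schema: `subject_id`,
#'   `group`, `keyword`, `valence`, `arousal`, one row per subject x
#'   keyword).
#' @param var_equal Use the Student (pooled-variance) form if `TRUE`.
#' @param adjust Multiple-testing correction passed to
#'   [stats::p.adjust()] within each axis; `"none"` (default) reports raw
#'   per-keyword p-values.
#' @return A `comparison_report`: data.frame with one row per keyword x
#'   axis and columns `keyword`, `axis`, `t_statistic`, `p_value`,
#'   `tier`, `mean_photograph`, `mean_artwork`, `n_photograph`,
#'   `n_artwork`.
#' @export
compare_groups <- function(responses, var_equal = FALSE, adjust = "none") {
  groups <- unique(responses$group)
  if (!all(c("photograph", "artwork") %in% groups)) {
    invalid_argument("responses must contain both a photograph and an artwork group")
  }
  keywords <- unique(responses$keyword)
  rows <- list()
  for (axis in c("valence", "arousal")) {
    for (kw in keywords) {
      ph <- responses[responses$group == "photograph" &
                        responses$keyword == kw, axis]
      aw <- responses[responses$group == "artwork" &
                        responses$keyword == kw, axis]
      tt <- keyword_ttest(ph, aw, var_equal = var_equal)
      rows[[paste(axis, kw)]] <- data.frame(
        keyword = kw, axis = axis,
        t_statistic = tt$t_statistic, p_value = tt$p_value,
        mean_photograph = tt$mean_photograph, mean_artwork = tt$mean_artwork,
        n_photograph = length(ph), n_artwork = length(aw),
        stringsAsFactors = FALSE
      )
    }
  }
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  if (adjust != "none") {
    for (axis in c("valence", "arousal")) {
      sel <- rep$axis == axis
      rep$p_value[sel] <- stats::p.adjust(rep$p_value[sel], method = adjust)
    }
  }
  rep$tier <- significance_tier(rep$p_value)
  class(rep) <- c("comparison_report", "data.frame")
  rep
}

#' Reshape a comparison report into the published 2 x 9 matrix layout
#'
#' @param report A `comparison_report`.
#' @return Matrix of p-values with rows `valence`/`arousal` and one
#'   column per keyword.
#' @export
report_matrix <- function(report) {
  keywords <- unique(report$keyword)
  m <- matrix(NA_real_, 2, length(keywords),
              dimnames = list(c("valence", "arousal"), keywords))
  for (i in seq_len(nrow(report))) {
    m[report$axis[i], report$keyword[i]] <- report$p_value[i]
  }
  m
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Per-keyword two-group comparison (photograph vs artwork)\n\n")
  m <- report_matrix(x)
  print(signif(m, 3))
  cat("\n")
  for (axis in c("valence", "arousal")) {
    sel <- x[x$axis == axis, ]
    for (tier in c("p<0.01", "p<0.05")) {
      kws <- sel$keyword[sel$tier == tier]
      if (length(kws) > 0) {
        cat(sprintf("%s significant at %s: %s\n", axis, tier,
                    paste(kws, collapse = ", ")))
      }
    }
    ns <- sel$keyword[sel$tier == "ns"]
    if (length(ns) > 0) {
      cat(sprintf("%s not significant: %s\n", axis, paste(ns, collapse = ", ")))
    }
  }
  invisible(x)
}

#' Calibrate the group test by simulation
#'
#' Estimates the empirical type-I error rate (under zero effect) and the
#' power (under the configured effect sizes) of the per-keyword test by
#' repeatedly simulating response tables and counting rejections at
#' `alpha`. Rejections are pooled over the nine keywords of the tested
#' axis.
#'
#' @param config A [sim_config()]; its effect sizes define the
#'   alternative.
#' @param n_reps Simulation replicates for the null (at least 100).
#' @param n_reps_power Replicates for the power estimate (defaults to
#'   `n_reps`).
#' @param alpha Nominal level (default 0.05).
#' @param axis Axis whose per-keyword scores are tested (default
#'   `"valence"`).
#' @return List with `type_I_rate`, `power`, `n_reps`, `alpha`.
#' @export
calibrate_test <- function(config, n_reps = 1000L, alpha = 0.05,
                           axis = "valence", n_reps_power = n_reps) {
  stopifnot(inherits(config, "sim_config"))
  if (n_reps < 100 || n_reps_power < 100) {
    invalid_argument("n_reps must be >= 100")
  }
  run_reps <- function(cfg, tag, reps) {
    rej <- logical(0)
    for (r in seq_len(reps)) {
      cfg$seed <- substream_seed(config$seed, "calibrate", tag, r)
      tab <- simulate_response_tables(cfg)
      for (kw in unique(tab$keyword)) {
        ph <- tab[tab$group == "photograph" & tab$keyword == kw, axis]
        aw <- tab[tab$group == "artwork" & tab$keyword == kw, axis]
        rej <- c(rej, keyword_ttest(ph, aw)$p_value < alpha)
      }
    }
    mean(rej)
  }
  null_cfg <- config
  null_cfg$valence_effect_size <- 0
  null_cfg$arousal_effect_size <- 0
  list(type_I_rate = run_reps(null_cfg, "null", n_reps),
       power = run_reps(config, "alt", n_reps_power),
       n_reps = n_reps, alpha = alpha)
}
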