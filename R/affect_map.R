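#' Map an affect score to the nearest emotion keyword
#'
#' Classifies a (valence, arousal) point to the keyword whose coordinates
#' minimize Euclidean distance in the affect plane. Ties are broken
#' deterministically by table order.
#'
#' @param score An `affect_score`, or a numeric vector
#'   `c(valence, arousal)`.
#' @param table Keyword coordinate table with columns `keyword`,
#'   `valence`, `arousal` (default [emotion_keywords()]).
#' @return One row of `table` (as a list) with an added `distance` field.
#' @export
#' @examples
#' map_to_keyword(c(0.9, 0.9))$keyword
map_to_keyword <- function(score, table = emotion_keywords()) {
  if (is.null(table) || nrow(table) == 0) {
    invalid_argument("keyword table must be non-empty")
  }
  if (inherits(score, "affect_score")) score <- c(score$valence, score$arousal)
  d2 <- (table$valence - score[1])^2 + (table$arousal - score[2])^2
  i <- which.min(d2)  # which.min returns the first minimum: table-order tie-break
  list(keyword = table$keyword[i], valence = table$valence[i],
       arousal = table$arousal[i], distance = sqrt(d2[i]))
}

#' Assemble per-subject response tables from trial scores
#'
#' Collects each subject's per-clip affect scores into one response per
#' keyword. Only clips of the subject's own medium are kept (the
#' photograph group is scored on photograph clips, the artwork group on
#' artwork clips); if a subject has several clips of the same keyword the
#' scores are averaged with a warning; a subject missing any keyword is
#' an error naming the subject and keyword.
#'
#' @param trial_scores Data.frame with columns `subject_id`, `group`,
#'   `medium`, `keyword`, `valence`, `arousal` — one row per scored clip.
#'   If `medium` is absent all clips are treated as the subject's medium.
#' @param keywords Character vector of required keywords (default the
#'   nine standard ones).
#' @return Data.frame with one row per subject x keyword and columns
#'   `subject_id`, `group`, `keyword`, `valence`, `arousal` (the shared
#'   response-table schema).
#' @export
assemble_responses <- function(trial_scores,
                               keywords = emotion_keywords()$keyword) {
  empty <- data.frame(subject_id = character(0), group = character(0),
                      keyword = character(0), valence = numeric(0),
                      arousal = numeric(0), stringsAsFactors = FALSE)
  if (is.null(trial_scores) || nrow(trial_scores) == 0) return(empty)
  ts <- trial_scores
  if ("medium" %in% names(ts)) ts <- ts[ts$medium == ts$group, , drop = FALSE]
  out <- list()
  for (sid in unique(ts$subject_id)) {
    rows <- ts[ts$subject_id == sid, , drop = FALSE]
    miss <- setdiff(keywords, rows$keyword)
    if (length(miss) > 0) {
      stop_eegaffect("incomplete_subject",
                     sprintf("subject %s is missing keyword(s): %s",
                             sid, paste(miss, collapse = ", ")),
                     subject_id = sid, missing_keywords = miss)
    }
    per_kw <- lapply(keywords, function(kw) {
      r <- rows[rows$keyword == kw, , drop = FALSE]
      if (nrow(r) > 1) {
        warning(sprintf("subject %s has %d clips for keyword '%s'; averaging",
                        sid, nrow(r), kw))
      }
      data.frame(subject_id = sid, group = rows$group[1], keyword = kw,
                 valence = mean(r$valence), arousal = mean(r$arousal),
                 stringsAsFactors = FALSE)
    })
    out[[sid]] <- do.call(rbind, per_kw)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
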