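#' The nine Russell-model emotion keywords and their default coordinates
#'
#' Returns the default placement of the nine emotion keywords in the
#' valence-arousal plane. The keyword set is fixed; the numeric coordinates
#' are package conventions chosen to respect quadrant membership
#' (positive-valence: excited, happy, pleased, peaceful, calm;
#' high-arousal: excited, happy, fear, suspense; low-arousal: peaceful,
#' calm, gloomy, sad) and may be overridden wherever a keyword table is
#' accepted.
#'
#' @return A data.frame with columns `keyword`, `valence`, `arousal`
#'   (both coordinates in `[-1, 1]`), one row per keyword.
#' @export
#' @examples
#' emotion_keywords()
emotion_keywords <- function() {
  data.frame(
    keyword = c("excited", "happy", "pleased", "peaceful", "calm",
                "gloomy", "sad", "fear", "suspense"),
    valence = c(0.45, 0.75, 0.90, 0.60, 0.80, -0.60, -0.80, -0.70, -0.45),
    arousal = c(0.85, 0.55, 0.10, -0.55, -0.30, -0.55, -0.30, 0.65, 0.85),
    stringsAsFactors = FALSE
  )
}

#' DEAP 32-channel electrode order
#'
#' The published channel ordering of the 32-channel DEAP recordings
#' (Geneva convention, 10/20 electrode names). Preprocessing reorders
#' sessions into this order so downstream stages see a fixed montage.
#'
#' @return Character vector of 32 electrode labels.
#' @export
deap_channel_order <- function() {
  c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
    "CP5", "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz",
    "Fp2", "AF4", "Fz", "F4", "F8", "FC6", "FC2", "Cz",
    "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2")
}

#' Published per-keyword p-values from the photograph/artwork study
#'
#' Loads the published two-group p-values (nine keywords x two axes) that
#' ship with the package as a plain-text fixture. These depend on the
#' original human recordings and are used only as inputs to the
#' significance-tiering logic, never as reproduction targets.
#'
#' @return A data.frame with columns `keyword`, `axis`, `p_value`.
#' @export
published_keyword_pvalues <- function() {
  path <- system.file("extdata", "published_pvalues.csv",
                      package = "eegaffect", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
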