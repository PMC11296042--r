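#' Default rating-scale roster
#'
#' The 28 rating scales used throughout the package, with a family tag
#' (basic-emotion word, commonly used affective scale, or biologically
#' inspired feature), a short plain-language definition, and flags recording
#' which study arm administers the scale: all 28 are rated for evoked
#' (narrative/video) emotions, while six are dropped for real-life sampling
#' as inapplicable or too demanding in a long survey. Five scales are flagged
#' as low-reliability exclusions, leaving 23 evoked and 18 real-life scales;
#' the 18 real-life scales are exactly the roster shared by all three
#' domains.
#'
#' @param domain `"all"` (default), `"evoked"` or `"real_life"`; the latter
#'   two restrict to scales administered in that arm.
#' @param post_exclusion if `TRUE`, drop the five low-reliability scales.
#' @return A tibble with columns `scale_id`, `family`, `definition`,
#'   `evoked`, `real_life`, `low_quality`.
#' @examples
#' nrow(scale_roster())                                   # 28
#' nrow(scale_roster("evoked", post_exclusion = TRUE))    # 23
#' nrow(scale_roster("real_life", post_exclusion = TRUE)) # 18
#' @export
scale_roster <- function(domain = c("all", "evoked", "real_life"),
                         post_exclusion = FALSE) {
  domain <- match.arg(domain)
  out <- emospace_scales
  if (domain == "evoked") out <- out[out$evoked, ]
  if (domain == "real_life") out <- out[out$real_life, ]
  if (post_exclusion) out <- out[!out$low_quality, ]
  out
}

# Scales never administered in the real-life (experience-sampling) arm.
.not_real_life <- c("approach", "relief", "self_relevance", "scalability",
                    "generalizability_stimuli", "generalizability_behavior")

# The five scales excluded for low reliability.
.low_quality_scales <- c("self_relevance", "intrinsic_extrinsic",
                         "remembering", "mental_bodily", "future")

emospace_scales <- local({
  def <- function(id, family, text) {
    tibble::tibble(scale_id = id, family = family, definition = text)
  }
  basic <- dplyr::bind_rows(
    def("happy", "basic", "Describes the degree to which you feel happy."),
    def("sad", "basic", "Describes the degree to which you feel sad."),
    def("afraid", "basic", "Describes the degree to which you feel afraid."),
    def("angry", "basic", "Describes the degree to which you feel angry."),
    def("surprised", "basic", "Describes the degree to which you feel surprised."),
    def("disgusted", "basic", "Describes the degree to which you feel disgusted.")
  )
  affective <- dplyr::bind_rows(
    def("valence", "affective", "Describes how pleasant or unpleasant the experience feels overall."),
    def("arousal", "affective", "Describes how activated or calm the experience makes you feel."),
    def("intensity", "affective", "Describes how strong the experience feels."),
    def("safety", "affective", "Describes how safe or threatened the situation makes you feel."),
    def("fairness", "affective", "Describes how fair or unfair the situation feels."),
    def("approach", "affective", "Describes the urge to approach or to avoid what is happening."),
    def("relief", "affective", "Describes how you feel at the end compared with the beginning."),
    def("worried", "affective", "Describes the degree to which you feel worried about what may happen."),
    def("moral_disgust", "affective", "Describes disgust at the conduct of a person rather than at a physical thing."),
    def("self_relevance", "affective", "Describes the level of relevance the experience has to your own life."),
    def("intrinsic_extrinsic", "affective", "Describes whether the experience reflects yourself or the surrounding situation."),
    def("remembering", "affective", "Describes the degree to which the experience involves remembering past events."),
    def("future", "affective", "Describes the degree to which the experience involves anticipating future events."),
    def("mental_bodily", "affective", "Describes the extent to which the experience is felt in the mind or in the body.")
  )
  biological <- dplyr::bind_rows(
    def("persistence", "biological", "Describes how long the experience lasts after what caused it ends."),
    def("common", "biological", "Describes how often an experience like this occurs in daily life."),
    def("control", "biological", "Describes how much the experience takes over what you do next."),
    def("scalability", "biological", "Describes whether the experience comes in many strengths or is all or none."),
    def("generalizability_stimuli", "biological", "Describes whether many different situations could cause this experience."),
    def("generalizability_behavior", "biological", "Describes whether the experience could lead to many different actions."),
    def("purity", "biological", "Describes whether the experience is a single feeling or a blend of several."),
    def("shareability", "biological", "Describes how readily the experience could be communicated to another person.")
  )
  out <- dplyr::bind_rows(basic, affective, biological)
  out$evoked <- TRUE
  out$real_life <- !(out$scale_id %in% .not_real_life)
  out$low_quality <- out$scale_id %in% .low_quality_scales
  out
})

#' The six basic-emotion scale identifiers
#' @return Character vector of length 6.
#' @export
basic_emotion_scales <- function() {
  c("happy", "surprised", "afraid", "angry", "disgusted", "sad")
}
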