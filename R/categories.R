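#' The articulator event vocabulary
#'
#' The annotation scheme codes facial and head articulations with 17 event
#' categories grouped by articulator: brow position (up/down), eye blinks,
#' mouth aperture (open/closed), mouth shape (round/flat/other), teeth
#' visibility (closed/open/touching lip), and the three head rotations
#' (turns, tilts, up/down movements). Categories within one articulator
#' group are mutually exclusive in time: the brows cannot be up and down
#' simultaneously, so no co-temporal relation between two same-group
#' categories is physically realizable.
#'
#' @return A data frame with one row per category and columns
#'   \code{name} (machine label), \code{group} (articulator group) and
#'   \code{display} (human-readable label used in reports).
#' @examples
#' cats <- feature_categories()
#' table(cats$group)
#' @export
feature_categories <- function() {
  data.frame(
    name = c(
      "brows_up", "brows_down",
      "blink",
      "mouth_open", "mouth_closed",
      "mouth_round", "mouth_flat", "mouth_other",
      "teeth_closed", "teeth_open", "teeth_touch_lip",
      "head_turn_left", "head_turn_right",
      "head_tilt_left", "head_tilt_right",
      "head_move_up", "head_move_down"
    ),
    group = c(
      "brows", "brows",
      "blink",
      "mouth_aperture", "mouth_aperture",
      "mouth_shape", "mouth_shape", "mouth_shape",
      "teeth", "teeth", "teeth",
      "head_turn", "head_turn",
      "head_tilt", "head_tilt",
      "head_move", "head_move"
    ),
    display = c(
      "Brows move up", "Brows move down",
      "Blink",
      "Mouth open", "Mouth closed",
      "Mouth shape round", "Mouth shape flat", "Mouth shape other",
      "Teeth closed", "Teeth open", "Teeth touch lip",
      "Head turns left", "Head turns right",
      "Head tilts left", "Head tilts right",
      "Head moves up", "Head moves down"
    ),
    stringsAsFactors = FALSE
  )
}

#' Map category names to their articulator group
#'
#' @param categories character vector of category names.
#' @return character vector of group labels.
#' @export
category_group <- function(categories) {
  cats <- feature_categories()
  idx <- match(categories, cats$name)
  if (anyNA(idx)) {
    stop("unknown feature category: ",
         paste(unique(categories[is.na(idx)]), collapse = ", "))
  }
  cats$group[idx]
}

#' Human-readable label for a category
#' @param categories character vector of category names.
#' @return character vector of display labels.
#' @export
category_display <- function(categories) {
  cats <- feature_categories()
  idx <- match(categories, cats$name)
  if (anyNA(idx)) {
    stop("unknown feature category: ",
         paste(unique(categories[is.na(idx)]), collapse = ", "))
  }
  cats$display[idx]
}

#' The five construction types and three polarity values
#'
#' Sentences carry one of five construction labels; every construction has
#' positive and negative polarity except Yes/no questions, which are
#' polarity-neutral, giving 9 sentence classes in total.
#' @return list with elements \code{constructions} and \code{polarities}.
#' @export
sentence_labels <- function() {
  list(
    constructions = c("hypothetical_conditional", "yes_no_question",
                      "wh_question", "wh_question_postposed", "assertion"),
    polarities = c("positive", "negative", "neutral")
  )
}

#' Combined class label (construction x polarity)
#' @param construction,polarity character vectors.
#' @return character vector like \code{"wh_question:negative"}.
#' @export
class_label <- function(construction, polarity) {
  paste(construction, polarity, sep = ":")
}
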