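#' Construct an annotated sentence
#'
#' An annotated sentence is one signed sentence: its time span, its class
#' labels (construction type and polarity) and the articulator events
#' observed inside it. All times are in seconds. Events crossing the
#' sentence boundary are clipped to the span; overlapping or abutting events
#' of the same category are merged into a single excursion (duplicated or
#' fragmented annotations of one articulator excursion are coder noise).
#'
#' @param sentence_id,signer_id character scalars.
#' @param construction one of the five construction labels
#'   (see [sentence_labels()]).
#' @param polarity `"positive"`, `"negative"` or `"neutral"`. Yes/no
#'   questions must be (and default to) `"neutral"`; no other construction
#'   may be neutral.
#' @param span numeric length-2, sentence onset/offset in seconds.
#' @param events data frame with columns `category`, `onset`, `offset`
#'   (seconds). May have zero rows.
#' @return An object of class `atl_sentence`.
#' @export
atl_sentence <- function(sentence_id, signer_id, construction, polarity = NULL,
                         span, events = empty_events()) {
  labs <- sentence_labels()
  if (!construction %in% labs$constructions) {
    stop("unknown construction label: ", construction)
  }
  if (is.null(polarity)) {
    polarity <- if (construction == "yes_no_question") "neutral" else "positive"
  }
  if (!polarity %in% labs$polarities) {
    stop("unknown polarity label: ", polarity)
  }
  if ((construction == "yes_no_question") != (polarity == "neutral")) {
    stop("polarity must be 'neutral' if and only if construction is ",
         "'yes_no_question' (got ", construction, " / ", polarity, ")")
  }
  span <- as.numeric(span)
  if (length(span) != 2L || !all(is.finite(span)) || span[1] >= span[2]) {
    stop("span must be a finite (onset, offset) pair with onset < offset")
  }
  events <- validate_events(events)
  # clip to span, drop events falling entirely outside
  events$onset <- pmax(events$onset, span[1])
  events$offset <- pmin(events$offset, span[2])
  events <- events[events$onset < events$offset, , drop = FALSE]
  events <- merge_same_category(events)
  structure(
    list(sentence_id = as.character(sentence_id),
         signer_id = as.character(signer_id),
         construction = construction,
         polarity = polarity,
         span = span,
         events = events),
    class = "atl_sentence"
  )
}

empty_events <- function() {
  data.frame(category = character(), onset = numeric(), offset = numeric(),
             stringsAsFactors = FALSE)
}

validate_events <- function(events) {
  stopifnot(is.data.frame(events))
  need <- c("category", "onset", "offset")
  if (!all(need %in% names(events))) {
    stop("events must have columns category, onset, offset")
  }
  events <- events[, need, drop = FALSE]
  events$category <- as.character(events$category)
  events$onset <- as.numeric(events$onset)
  events$offset <- as.numeric(events$offset)
  if (nrow(events)) {
    category_group(events$category)  # errors on unknown categories
    bad <- !(events$onset < events$offset)
    if (any(bad)) {
      stop("event intervals must have strictly positive duration (rows ",
           paste(which(bad), collapse = ", "), ")")
    }
  }
  rownames(events) <- NULL
  events
}

#' Merge overlapping or abutting same-category events
#'
#' Interval union per category. The result is sorted by onset then category
#' and is invariant under permutation of the input rows, which makes the
#' merge associative and order-independent.
#'
#' @param events event data frame (`category`, `onset`, `offset`).
#' @return merged event data frame.
#' @export
merge_same_category <- function(events) {
  if (nrow(events) <= 1L) {
    out <- events[order(events$onset, events$category), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  pieces <- lapply(split(events, events$category), function(ev) {
    ev <- ev[order(ev$onset, ev$offset), , drop = FALSE]
    ons <- ev$onset
    offs <- ev$offset
    keep_on <- ons[1]
    keep_off <- offs[1]
    res_on <- numeric(0)
    res_off <- numeric(0)
    for (i in seq_len(nrow(ev))[-1]) {
      if (ons[i] <= keep_off) {   # overlap or touch: extend
        keep_off <- max(keep_off, offs[i])
      } else {
        res_on <- c(res_on, keep_on)
        res_off <- c(res_off, keep_off)
        keep_on <- ons[i]
        keep_off <- offs[i]
      }
    }
    data.frame(category = ev$category[1],
               onset = c(res_on, keep_on),
               offset = c(res_off, keep_off),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$onset, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.atl_sentence <- function(x, ...) {
  cat(sprintf("<atl_sentence %s> signer=%s %s/%s span=[%.3f, %.3f] events=%d\n",
              x$sentence_id, x$signer_id, x$construction, x$polarity,
              x$span[1], x$span[2], nrow(x$events)))
  invisible(x)
}

#' Construct a corpus of annotated sentences
#'
#' @param sentences list of [atl_sentence()] objects.
#' @return An object of class `atl_corpus` with elements `sentences` and
#'   `class_counts` (table of construction:polarity class labels).
#' @export
atl_corpus <- function(sentences) {
  stopifnot(is.list(sentences))
  ok <- vapply(sentences, inherits, logical(1), "atl_sentence")
  if (!all(ok)) stop("all elements must be atl_sentence objects")
  cls <- vapply(sentences, function(s) class_label(s$construction, s$polarity),
                character(1))
  structure(
    list(sentences = sentences,
         class_counts = if (length(cls)) table(cls) else table(character())),
    class = "atl_corpus"
  )
}

#' @export
print.atl_corpus <- function(x, ...) {
  cat(sprintf("<atl_corpus> %d sentences, %d classes\n",
              length(x$sentences), length(x$class_counts)))
  if (length(x$class_counts)) print(x$class_counts)
  invisible(x)
}

#' @export
length.atl_corpus <- function(x) length(x$sentences)

#' Per-sentence metadata of a corpus
#'
#' @param corpus an `atl_corpus`.
#' @return data frame with columns `sentence_id`, `signer_id`,
#'   `construction`, `polarity`, `class`, `onset`, `offset`, `n_events`.
#' @export
corpus_metadata <- function(corpus) {
  stopifnot(inherits(corpus, "atl_corpus"))
  do.call(rbind, lapply(corpus$sentences, function(s) {
    data.frame(sentence_id = s$sentence_id, signer_id = s$signer_id,
               construction = s$construction, polarity = s$polarity,
               class = class_label(s$construction, s$polarity),
               onset = s$span[1], offset = s$span[2],
               n_events = nrow(s$events), stringsAsFactors = FALSE)
  }))
}
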