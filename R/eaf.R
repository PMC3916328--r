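#' Read annotated sentences from an ELAN EAF file
#'
#' Parses the `TIME_ORDER`/`TIME_SLOT` table (integer milliseconds) and the
#' alignable annotations of the mapped tiers. Sentence spans come from the
#' annotations of `sentence_tier`; the annotation value of a sentence-tier
#' annotation is used as the sentence id (falling back to the annotation
#' id when empty). Event annotations are converted to seconds, assigned to
#' the sentence whose span contains their midpoint, and clipped to that
#' span. Annotations on tiers not named in `tier_map` are skipped with a
#' warning, as are events not contained in any sentence span.
#'
#' Construction and polarity labels are not stored in EAF; they are joined
#' from `manifest` (columns `sentence_id`, `construction`, `polarity`).
#' Without a manifest every sentence is labelled as a positive assertion,
#' which is only adequate for relation extraction, not for discriminant
#' analysis.
#'
#' @param path EAF file path.
#' @param tier_map named character vector or list mapping tier id to
#'   feature-category name.
#' @param sentence_tier tier id holding the sentence spans.
#' @param manifest optional data frame with sentence labels.
#' @return list of [atl_sentence()] objects.
#' @export
read_eaf <- function(path, tier_map, sentence_tier, manifest = NULL) {
  doc <- xml2::read_xml(path)
  tier_map <- unlist(tier_map)
  if (length(tier_map)) category_group(tier_map)  # validate categories

  slots <- xml2::xml_find_all(doc, ".//TIME_ORDER/TIME_SLOT")
  slot_id <- xml2::xml_attr(slots, "TIME_SLOT_ID")
  slot_val <- xml2::xml_attr(slots, "TIME_VALUE")
  slot_time <- suppressWarnings(as.numeric(slot_val)) / 1000  # ms -> s
  names(slot_time) <- slot_id

  slot_lookup <- function(ref, ann_id) {
    t <- slot_time[ref]
    if (is.na(t)) {
      stop("annotation ", ann_id, " references time slot ", ref,
           " with no time value")
    }
    unname(t)
  }

  read_tier <- function(tier) {
    anns <- xml2::xml_find_all(tier, ".//ALIGNABLE_ANNOTATION")
    if (!length(anns)) return(NULL)
    ids <- xml2::xml_attr(anns, "ANNOTATION_ID")
    data.frame(
      ann_id = ids,
      onset = vapply(seq_along(anns), function(i)
        slot_lookup(xml2::xml_attr(anns[[i]], "TIME_SLOT_REF1"), ids[i]),
        numeric(1)),
      offset = vapply(seq_along(anns), function(i)
        slot_lookup(xml2::xml_attr(anns[[i]], "TIME_SLOT_REF2"), ids[i]),
        numeric(1)),
      value = vapply(anns, function(a)
        trimws(paste(xml2::xml_text(xml2::xml_find_all(a, ".//ANNOTATION_VALUE")),
                     collapse = " ")), character(1)),
      stringsAsFactors = FALSE)
  }

  tiers <- xml2::xml_find_all(doc, ".//TIER")
  tier_ids <- xml2::xml_attr(tiers, "TIER_ID")
  if (!sentence_tier %in% tier_ids) {
    stop("sentence tier '", sentence_tier, "' not found in ", path)
  }

  sent_tab <- read_tier(tiers[[match(sentence_tier, tier_ids)]])
  if (is.null(sent_tab)) return(list())
  sent_tab$sentence_id <- ifelse(nzchar(sent_tab$value), sent_tab$value,
                                 sent_tab$ann_id)
  signer <- xml2::xml_attr(tiers[[match(sentence_tier, tier_ids)]],
                           "PARTICIPANT")
  if (is.na(signer) || !nzchar(signer)) signer <- "unknown"

  unmapped <- setdiff(tier_ids, c(names(tier_map), sentence_tier))
  if (length(unmapped)) {
    warning("skipping unmapped tiers: ", paste(unmapped, collapse = ", "))
  }

  events <- do.call(rbind, lapply(intersect(names(tier_map), tier_ids),
    function(tid) {
      tab <- read_tier(tiers[[match(tid, tier_ids)]])
      if (is.null(tab)) return(NULL)
      tab$category <- unname(tier_map[[tid]])
      tab
    }))

  lookup_labels <- function(sid) {
    if (!is.null(manifest)) {
      hit <- match(sid, manifest$sentence_id)
      if (!is.na(hit)) {
        return(list(construction = manifest$construction[hit],
                    polarity = manifest$polarity[hit]))
      }
    }
    list(construction = "assertion", polarity = "positive")
  }

  sentences <- lapply(seq_len(nrow(sent_tab)), function(i) {
    sp <- c(sent_tab$onset[i], sent_tab$offset[i])
    ev <- empty_events()
    if (!is.null(events) && nrow(events)) {
      mid <- (events$onset + events$offset) / 2
      inside <- mid >= sp[1] & mid <= sp[2]
      ev <- events[inside, c("category", "onset", "offset"), drop = FALSE]
    }
    lab <- lookup_labels(sent_tab$sentence_id[i])
    atl_sentence(sentence_id = sent_tab$sentence_id[i], signer_id = signer,
                 construction = lab$construction, polarity = lab$polarity,
                 span = sp, events = ev)
  })

  if (!is.null(events) && nrow(events)) {
    spans <- cbind(sent_tab$onset, sent_tab$offset)
    mid <- (events$onset + events$offset) / 2
    covered <- vapply(mid, function(m)
      any(m >= spans[, 1] & m <= spans[, 2]), logical(1))
    if (any(!covered)) {
      warning(sum(!covered),
              " event annotation(s) outside every sentence span skipped")
    }
  }
  sentences
}
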