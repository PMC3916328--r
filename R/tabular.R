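#' Write a corpus to the tabular interval format
#'
#' Plain UTF-8, tab-separated, one header row. Columns: `kind` (`span` for
#' the sentence-span row, `event` for articulator events), `sentence_id`,
#' `signer_id`, `construction`, `polarity`, `category` (empty on span rows),
#' `onset`, `offset` (seconds, printed with 9 decimal places so that
#' millisecond-resolution times round-trip exactly).
#'
#' @param corpus an [atl_corpus()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tabular <- function(corpus, path) {
  stopifnot(inherits(corpus, "atl_corpus"))
  rows <- lapply(corpus$sentences, function(s) {
    span_row <- data.frame(
      kind = "span", sentence_id = s$sentence_id, signer_id = s$signer_id,
      construction = s$construction, polarity = s$polarity,
      category = "", onset = s$span[1], offset = s$span[2],
      stringsAsFactors = FALSE)
    if (nrow(s$events)) {
      ev_rows <- data.frame(
        kind = "event", sentence_id = s$sentence_id, signer_id = s$signer_id,
        construction = s$construction, polarity = s$polarity,
        category = s$events$category,
        onset = s$events$onset, offset = s$events$offset,
        stringsAsFactors = FALSE)
      rbind(span_row, ev_rows)
    } else {
      span_row
    }
  })
  tab <- do.call(rbind, rows)
  tab$onset <- sprintf("%.9f", tab$onset)
  tab$offset <- sprintf("%.9f", tab$offset)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a corpus from the tabular interval format
#'
#' Inverse of [write_tabular()]; the round trip is lossless for
#' millisecond-resolution times. Labels and categories are validated; an
#' unknown category or construction is a hard error naming the offending
#' row.
#'
#' @param path input file path.
#' @return an [atl_corpus()].
#' @export
read_tabular <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           fileEncoding = "UTF-8")
  need <- c("kind", "sentence_id", "signer_id", "construction", "polarity",
            "category", "onset", "offset")
  if (!all(need %in% names(tab))) {
    stop("tabular file must have columns: ", paste(need, collapse = ", "))
  }
  tab$onset <- as.numeric(tab$onset)
  tab$offset <- as.numeric(tab$offset)
  labs <- sentence_labels()
  cats <- feature_categories()$name
  # data row i is file line i + 1 (header)
  bad <- which(!tab$construction %in% labs$constructions)
  if (length(bad)) {
    stop("unknown construction '", tab$construction[bad[1]], "' at data row ",
         bad[1])
  }
  bad <- which(tab$kind == "event" & !tab$category %in% cats)
  if (length(bad)) {
    stop("unknown category '", tab$category[bad[1]], "' at data row ", bad[1])
  }
  bad <- which(!(tab$onset < tab$offset))
  if (length(bad)) {
    stop("onset >= offset at data row ", bad[1])
  }
  span_rows <- tab[tab$kind == "span", , drop = FALSE]
  if (anyDuplicated(span_rows$sentence_id)) {
    stop("duplicated span row for sentence ",
         span_rows$sentence_id[duplicated(span_rows$sentence_id)][1])
  }
  ev_rows <- tab[tab$kind == "event", , drop = FALSE]
  orphan <- setdiff(unique(ev_rows$sentence_id), span_rows$sentence_id)
  if (length(orphan)) {
    stop("event rows without a span row for sentence ", orphan[1])
  }
  sentences <- lapply(seq_len(nrow(span_rows)), function(i) {
    sp <- span_rows[i, ]
    ev <- ev_rows[ev_rows$sentence_id == sp$sentence_id, , drop = FALSE]
    atl_sentence(
      sentence_id = sp$sentence_id, signer_id = sp$signer_id,
      construction = sp$construction, polarity = sp$polarity,
      span = c(sp$onset, sp$offset),
      events = data.frame(category = ev$category, onset = ev$onset,
                          offset = ev$offset, stringsAsFactors = FALSE))
  })
  atl_corpus(sentences)
}
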