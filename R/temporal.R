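#' The seven interval propositions
#'
#' Relative temporal structure between two events is coded with seven Allen
#' interval propositions: `before`, `meets`, `overlaps`, `equals`, `starts`,
#' `during`, `finishes`. Inverse relations (after, met-by, ...) are not
#' separate labels: the classifier emits each pair in a canonical role
#' order, which subsumes them. `equals` doubles as the unary encoder — the
#' single occurrence of an event is coded as the event equalling itself.
#'
#' @return character vector of the 7 proposition names, in report order.
#' @export
propositions <- function() {
  c("before", "meets", "overlaps", "equals", "starts", "during", "finishes")
}

#' Classify an interval pair into an Allen proposition with tolerance
#'
#' Boundary equality is judged with tolerance `epsilon` (seconds): two
#' boundaries are equal when they differ by at most `epsilon`. This absorbs
#' acquisition noise — annotated excursions of different articulators never
#' abut to the frame, so an exact `meets` would almost never fire. The
#' decision tree, in precedence order on the pair ordered earliest start
#' first, is: \emph{equals} (both boundaries equal), \emph{starts} (starts
#' equal, one ends more than `epsilon` earlier; the shorter interval starts
#' the longer), \emph{finishes} (ends equal, starts distinct; the
#' later-starting interval finishes the other), \emph{during} (strict
#' containment with `epsilon` margins; contained interval first),
#' \emph{overlaps}, \emph{meets} (the first interval's offset equals the
#' second's onset within `epsilon`), \emph{before} (gap larger than
#' `epsilon`). The seven branches are exhaustive for every pair of
#' positive-duration intervals and any `epsilon >= 0`.
#'
#' @param a,b numeric length-2 intervals `(onset, offset)`, onset < offset.
#' @param epsilon non-negative tolerance in seconds.
#' @return list with `proposition` and `roles`, an integer pair giving which
#'   input (1 = `a`, 2 = `b`) plays the first and second role of the
#'   proposition. Symmetric under argument swap.
#' @examples
#' classify_pair(c(0, 2), c(5, 7), 0.1)$proposition    # "before"
#' classify_pair(c(0, 2), c(2.05, 4), 0.1)$proposition # "meets"
#' @export
classify_pair <- function(a, b, epsilon = 0.067) {
  stopifnot(length(a) == 2L, length(b) == 2L, epsilon >= 0)
  if (!(a[1] < a[2]) || !(b[1] < b[2])) {
    stop("intervals must have strictly positive duration")
  }
  # canonical order: earlier start first; ties earlier end first; else as given
  if (b[1] < a[1] || (b[1] == a[1] && b[2] < a[2])) {
    p <- b; q <- a; ip <- 2L; iq <- 1L
  } else {
    p <- a; q <- b; ip <- 1L; iq <- 2L
  }
  # all branch tests share these three differences, so one rounding of each
  # boundary comparison decides consistently across branches
  ds <- q[1] - p[1]   # start difference (>= 0 up to rounding)
  de <- q[2] - p[2]   # end difference
  gap <- q[1] - p[2]  # gap between p's offset and q's onset
  start_eq <- abs(ds) <= epsilon
  end_eq <- abs(de) <= epsilon
  if (start_eq && end_eq) {
    return(list(proposition = "equals", roles = c(ip, iq)))
  }
  if (start_eq) {
    # the interval ending > epsilon earlier starts the other
    if (de > 0) list(proposition = "starts", roles = c(ip, iq))
    else list(proposition = "starts", roles = c(iq, ip))
  } else if (end_eq) {
    # later-starting interval finishes the earlier-starting one
    list(proposition = "finishes", roles = c(iq, ip))
  } else if (de < -epsilon) {
    list(proposition = "during", roles = c(iq, ip))   # contained first
  } else if (gap < -epsilon) {
    # p reaches > epsilon past q's onset and ends > epsilon before q's end
    list(proposition = "overlaps", roles = c(ip, iq))
  } else if (gap <= epsilon) {
    list(proposition = "meets", roles = c(ip, iq))
  } else {
    list(proposition = "before", roles = c(ip, iq))
  }
}

#' Build the feasible relation space
#'
#' Enumerates every (first category, second category, proposition) triple
#' that can be observed, in a fixed deterministic order, and indexes them.
#' Included are: the 17 unary self-equals triples (one occurrence of an
#' event is coded as the event equalling itself); `before` and `meets` for
#' every ordered category pair including repeats of the same category
#' (sequences such as blink-before-blink or the two halves of a headshake
#' are meaningful); and the co-temporal propositions (`overlaps`, `equals`,
#' `starts`, `during`, `finishes`) only for category pairs from different
#' articulator groups — two categories of the same articulator (e.g. brows
#' up and brows down) are mutually exclusive in time, so their co-temporal
#' triples are infeasible and excluded. Binary `equals` triples, being
#' symmetric, are stored with the categories in vocabulary order.
#'
#' @param categories category data frame as from [feature_categories()];
#'   smaller vocabularies are allowed (used in tests).
#' @return object of class `atl_space`: list with `entries` (data frame
#'   `first`, `second`, `proposition`), `index` (environment mapping
#'   `"first|proposition|second"` keys to 1-based positions) and
#'   `categories`.
#' @export
build_feature_space <- function(categories = feature_categories()) {
  cats <- categories$name
  grp <- categories$group
  n <- length(cats)
  first <- character(0); second <- character(0); prop <- character(0)
  add <- function(f, s, p) {
    first <<- c(first, f); second <<- c(second, s); prop <<- c(prop, p)
  }
  # unary encoders first, in vocabulary order
  for (i in seq_len(n)) add(cats[i], cats[i], "equals")
  co_temporal <- c("overlaps", "equals", "starts", "during", "finishes")
  for (p in propositions()) {
    if (p %in% c("before", "meets")) {
      for (i in seq_len(n)) for (j in seq_len(n)) add(cats[i], cats[j], p)
    } else if (p == "equals") {
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i < j && grp[i] != grp[j]) add(cats[i], cats[j], p)
      }
    } else {
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i != j && grp[i] != grp[j]) add(cats[i], cats[j], p)
      }
    }
  }
  entries <- data.frame(first = first, second = second, proposition = prop,
                        stringsAsFactors = FALSE)
  index <- new.env(parent = emptyenv(), size = nrow(entries))
  keys <- paste(entries$first, entries$proposition, entries$second, sep = "|")
  for (k in seq_along(keys)) assign(keys[k], k, envir = index)
  structure(list(entries = entries, index = index, categories = categories),
            class = "atl_space")
}

#' @export
print.atl_space <- function(x, ...) {
  cat(sprintf("<atl_space> %d feasible relations over %d categories\n",
              nrow(x$entries), nrow(x$categories)))
  invisible(x)
}

space_lookup <- function(space, first, prop, second) {
  key <- paste(first, prop, second, sep = "|")
  if (exists(key, envir = space$index, inherits = FALSE)) {
    get(key, envir = space$index, inherits = FALSE)
  } else {
    NA_integer_
  }
}

#' Human-readable relation names
#'
#' Unary self-equals entries are labelled with the bare category name
#' ("Brows move up"); binary entries as "first \emph{proposition} second"
#' ("Head moves down finishes brows move up"), matching report row labels.
#'
#' @param space an `atl_space`.
#' @return character vector, one label per space entry.
#' @export
relation_names <- function(space) {
  e <- space$entries
  unary <- e$first == e$second & e$proposition == "equals"
  lab <- paste(category_display(e$first), e$proposition,
               sub("^(.)", "\\L\\1", category_display(e$second), perl = TRUE))
  lab[unary] <- category_display(e$first[unary])
  lab
}

#' Extract relation instances from one sentence
#'
#' Produces one unary self-equals instance per event occurrence, plus one
#' classified instance per unordered event pair whose triple is feasible.
#' Pairs classifying to an infeasible triple (same-articulator co-temporal
#' configurations, which can only arise from coder noise) are dropped, with
#' a warning when `warn_infeasible` is set. Binary `equals` instances are
#' stored with categories in vocabulary order to match the space.
#'
#' With `adjacent_only = TRUE`, `before`/`meets` instances between two
#' events of the \emph{same} category are kept only for consecutive
#' occurrences (three blinks yield two blink-before-blink instances instead
#' of three); all-pairs counting is the default.
#'
#' @param sentence an [atl_sentence()].
#' @param space an `atl_space`.
#' @param epsilon tolerance in seconds.
#' @param adjacent_only logical; see above.
#' @param warn_infeasible warn when an infeasible pair is dropped.
#' @return data frame with columns `first`, `proposition`, `second`,
#'   `onset1`, `offset1`, `onset2`, `offset2`, `space_index`.
#' @export
extract_relations <- function(sentence, space, epsilon = 0.067,
                              adjacent_only = FALSE, warn_infeasible = FALSE) {
  stopifnot(inherits(sentence, "atl_sentence"), inherits(space, "atl_space"))
  ev <- sentence$events
  nE <- nrow(ev)
  out_first <- character(0); out_prop <- character(0); out_second <- character(0)
  out_int <- matrix(numeric(0), ncol = 4)
  out_idx <- integer(0)
  dropped <- 0L
  emit <- function(f, p, s, i1, i2) {
    idx <- space_lookup(space, f, p, s)
    if (is.na(idx)) {
      dropped <<- dropped + 1L
      return(invisible(NULL))
    }
    out_first <<- c(out_first, f); out_prop <<- c(out_prop, p)
    out_second <<- c(out_second, s)
    out_int <<- rbind(out_int, c(ev$onset[i1], ev$offset[i1],
                                 ev$onset[i2], ev$offset[i2]))
    out_idx <<- c(out_idx, idx)
  }
  if (nE) {
    cat_pos <- match(ev$category, space$categories$name)
    # unary encoding: every occurrence equals itself
    for (i in seq_len(nE)) {
      emit(ev$category[i], "equals", ev$category[i], i, i)
    }
    if (nE >= 2L) {
      # rank of each event among same-category occurrences, by onset
      occ_rank <- stats::ave(ev$onset, ev$category, FUN = rank)
      for (i in seq_len(nE - 1L)) for (j in seq(i + 1L, nE)) {
        cl <- classify_pair(c(ev$onset[i], ev$offset[i]),
                            c(ev$onset[j], ev$offset[j]), epsilon)
        r <- ifelse(cl$roles == 1L, i, j)
        f <- ev$category[r[1]]; s <- ev$category[r[2]]
        p <- cl$proposition
        if (p == "equals" && !anyNA(cat_pos[r]) &&
            cat_pos[r[1]] > cat_pos[r[2]]) {
          tmp <- r[1]; r[1] <- r[2]; r[2] <- tmp
          f <- ev$category[r[1]]; s <- ev$category[r[2]]
        }
        if (adjacent_only && f == s && p %in% c("before", "meets") &&
            abs(occ_rank[i] - occ_rank[j]) != 1) {
          next
        }
        emit(f, p, s, r[1], r[2])
      }
    }
  }
  if (dropped && warn_infeasible) {
    warning(dropped, " event pair(s) with infeasible (same-articulator ",
            "co-temporal) relations dropped in sentence ",
            sentence$sentence_id)
  }
  data.frame(first = out_first, proposition = out_prop, second = out_second,
             onset1 = out_int[, 1], offset1 = out_int[, 2],
             onset2 = out_int[, 3], offset2 = out_int[, 4],
             space_index = out_idx, stringsAsFactors = FALSE)
}
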