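#' Count relation instances into a fixed-length histogram
#'
#' @param instances data frame from [extract_relations()].
#' @param space the `atl_space` the instances were extracted against.
#' @return integer vector of length `nrow(space$entries)`; entry j counts
#'   the instances mapping to space entry j.
#' @export
vectorize <- function(instances, space) {
  p <- nrow(space$entries)
  v <- integer(p)
  if (nrow(instances)) {
    if (anyNA(instances$space_index) ||
        any(instances$space_index < 1L | instances$space_index > p)) {
      stop("instance outside the feature space")
    }
    tab <- tabulate(instances$space_index, nbins = p)
    v <- as.integer(tab)
  }
  v
}

#' Presence indicator of a count vector
#'
#' @param v numeric vector or matrix of counts.
#' @return 0/1 object of the same shape; idempotent.
#' @export
binarize <- function(v) {
  out <- (v >= 1) * 1L
  if (is.matrix(v)) dim(out) <- dim(v)
  out
}

#' Featurize a corpus into a count matrix
#'
#' Runs relation extraction on every sentence and stacks the histograms
#' into an n-by-p matrix (p = number of feasible relations), with sentence
#' ids as row names and relation keys as column names.
#'
#' @param corpus an [atl_corpus()].
#' @param space an `atl_space`.
#' @param epsilon tolerance in seconds.
#' @param adjacent_only passed to [extract_relations()].
#' @return object of class `atl_features`: list with `counts` (matrix),
#'   `meta` ([corpus_metadata()] data frame), `space`, `epsilon`.
#' @export
featurize_corpus <- function(corpus, space = build_feature_space(),
                             epsilon = 0.067, adjacent_only = FALSE) {
  stopifnot(inherits(corpus, "atl_corpus"))
  n <- length(corpus$sentences)
  p <- nrow(space$entries)
  counts <- matrix(0L, nrow = n, ncol = p)
  for (i in seq_len(n)) {
    inst <- extract_relations(corpus$sentences[[i]], space, epsilon,
                              adjacent_only = adjacent_only)
    counts[i, ] <- vectorize(inst, space)
  }
  meta <- corpus_metadata(corpus)
  rownames(counts) <- meta$sentence_id
  colnames(counts) <- paste(space$entries$first, space$entries$proposition,
                            space$entries$second, sep = "|")
  structure(list(counts = counts, meta = meta, space = space,
                 epsilon = epsilon),
            class = "atl_features")
}

#' @export
print.atl_features <- function(x, ...) {
  cat(sprintf("<atl_features> %d sentences x %d relations (epsilon = %g s)\n",
              nrow(x$counts), ncol(x$counts), x$epsilon))
  invisible(x)
}

#' Build a binary contrast from a featurized corpus
#'
#' Two contrast types mirror the two experiments the pipeline is designed
#' for. `"construction"`: one construction versus all others, polarity
#' pooled (one-vs-all). `"polarity"`: positive versus negative sentences
#' within one construction; Yes/no questions are polarity-neutral and are
#' rejected. Class 1 is the target construction (or the positives).
#'
#' @param features an `atl_features`.
#' @param type `"construction"` or `"polarity"`.
#' @param target target construction label.
#' @return object of class `atl_contrast`: list with `X` (count matrix of
#'   retained sentences), `y` (factor, level order class1/class2),
#'   `class_names`, `space`.
#' @export
make_contrast <- function(features, type = c("construction", "polarity"),
                          target) {
  type <- match.arg(type)
  stopifnot(inherits(features, "atl_features"))
  labs <- sentence_labels()
  if (!target %in% labs$constructions) {
    stop("unknown construction label: ", target)
  }
  meta <- features$meta
  if (type == "construction") {
    keep <- rep(TRUE, nrow(meta))
    cls1 <- meta$construction == target
    class_names <- c(target, "others")
  } else {
    if (target == "yes_no_question") {
      stop("Yes/no questions are polarity-neutral; no polarity contrast")
    }
    keep <- meta$construction == target & meta$polarity != "neutral"
    cls1 <- meta$polarity == "positive"
    class_names <- c(paste0(target, ":positive"),
                     paste0(target, ":negative"))
  }
  X <- features$counts[keep, , drop = FALSE]
  y <- factor(ifelse(cls1[keep], "class1", "class2"),
              levels = c("class1", "class2"))
  if (any(table(y) == 0)) {
    stop("both classes must be non-empty for contrast ", class_names[1])
  }
  structure(list(X = X, y = y, class_names = class_names,
                 space = features$space),
            class = "atl_contrast")
}

#' @export
print.atl_contrast <- function(x, ...) {
  cat(sprintf("<atl_contrast> %s (n=%d) vs %s (n=%d), %d relations\n",
              x$class_names[1], sum(x$y == "class1"),
              x$class_names[2], sum(x$y == "class2"), ncol(x$X)))
  invisible(x)
}

#' Export a count matrix with human-readable relation headers
#'
#' Writes one header row of relation names (unary relations as the bare
#' category name) followed by integer counts per sentence, tab-separated.
#'
#' @param features an `atl_features`.
#' @param path output path.
#' @param drop_empty drop relations never observed in this corpus.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path, drop_empty = TRUE) {
  counts <- features$counts
  nm <- relation_names(features$space)
  if (drop_empty) {
    keep <- colSums(counts) > 0
    counts <- counts[, keep, drop = FALSE]
    nm <- nm[keep]
  }
  tab <- data.frame(sentence_id = rownames(counts), counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(tab) <- c("sentence_id", nm)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
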