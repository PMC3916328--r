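#' Ranked discriminant-relation report for a binary contrast
#'
#' The machine twin of a published discriminant-feature table: relations
#' ranked by their (LOSO-averaged) normalized discriminant weight, each with
#' its per-class activation rate, d-prime sensitivity, and one-dimensional
#' classification accuracy.
#'
#' @param m an `atl_contrast` built by [make_contrast()].
#' @param cfg an [rlda_config()].
#' @param top_k number of top-ranked relations to report.
#' @param rank_source `"loso"` averages the normalized weight vector over
#'   all leave-one-sentence-out iterations (slower, the reference
#'   procedure); `"fit"` ranks from a single fit on all sentences.
#' @return data frame of class `atl_report` with columns `relation`,
#'   `weight`, `activation_pct_class1`, `activation_pct_class2`, `dprime`,
#'   `classification_pct_class1`, `classification_pct_class2`; attributes
#'   `class_names`, `accuracy` (LOSO accuracy, `NA` for `rank_source =
#'   "fit"`) and `lam`.
#' @export
discriminant_report <- function(m, cfg = rlda_config(), top_k = 10L,
                                rank_source = c("loso", "fit")) {
  rank_source <- match.arg(rank_source)
  stopifnot(inherits(m, "atl_contrast"))
  lam <- cfg$lam
  if (is.null(lam)) lam <- select_lambda(m, cfg)$lam
  cfg_fix <- rlda_config(lam = lam, lam_grid = cfg$lam_grid,
                         cv_folds = cfg$cv_folds, seed = cfg$seed)
  if (rank_source == "loso") {
    ev <- loso_evaluate(m, cfg_fix)
    weights <- ev$weights
    accuracy <- ev$accuracy
  } else {
    fit <- rlda_direction(m, cfg_fix)
    weights <- fit$normalized_weights
    accuracy <- NA_real_
  }
  mw <- max(weights)
  wn <- if (mw > 0) weights / mw else weights
  ranking <- order(-wn, seq_along(wn))
  top <- ranking[seq_len(min(top_k, length(ranking)))]
  act <- activation_rates(m, top)
  cls <- t(vapply(top, function(j) per_feature_classification(m, j),
                  numeric(2)))
  rep_df <- data.frame(
    relation = relation_names(m$space)[top],
    weight = wn[top],
    activation_pct_class1 = act[, 1],
    activation_pct_class2 = act[, 2],
    dprime = dprime(m, top),
    classification_pct_class1 = cls[, 1],
    classification_pct_class2 = cls[, 2],
    stringsAsFactors = FALSE)
  rownames(rep_df) <- NULL
  structure(rep_df, class = c("atl_report", "data.frame"),
            class_names = m$class_names, accuracy = accuracy, lam = lam)
}

#' Write a discriminant report as CSV
#'
#' Columns: ATL relation, normalized weight (2 decimals), per-class
#' activation percentages (1 decimal), d-prime (2 decimals, `Inf` printed
#' as is), per-class classification percentages (1 decimal).
#'
#' @param report an `atl_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  cn <- attr(report, "class_names")
  out <- data.frame(
    `ATL relation` = report$relation,
    `Normalized weight` = sprintf("%.2f", report$weight),
    a1 = sprintf("%.1f", report$activation_pct_class1),
    a2 = sprintf("%.1f", report$activation_pct_class2),
    `d-prime` = ifelse(is.finite(report$dprime),
                       sprintf("%.2f", report$dprime), "Inf"),
    c1 = sprintf("%.1f", report$classification_pct_class1),
    c2 = sprintf("%.1f", report$classification_pct_class2),
    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[3:4] <- paste("% Activation in", cn)
  names(out)[6:7] <- paste("% Classification in", cn)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.atl_report <- function(x, ...) {
  cn <- attr(x, "class_names")
  cat(sprintf("Discriminant relations: %s vs %s", cn[1], cn[2]))
  if (!is.na(attr(x, "accuracy"))) {
    cat(sprintf(" (LOSO accuracy %.1f%%)", 100 * attr(x, "accuracy")))
  }
  cat("\n")
  print.data.frame(cbind(
    x["relation"],
    data.frame(weight = sprintf("%.2f", x$weight),
               act1 = sprintf("%.1f", x$activation_pct_class1),
               act2 = sprintf("%.1f", x$activation_pct_class2),
               dprime = ifelse(is.finite(x$dprime),
                               sprintf("%.2f", x$dprime), "Inf"),
               cls1 = sprintf("%.1f", x$classification_pct_class1),
               cls2 = sprintf("%.1f", x$classification_pct_class2))),
    right = FALSE)
  invisible(x)
}
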