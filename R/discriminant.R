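#' Configuration for the discriminant analysis
#'
#' @param lam fixed regularization value, or `NULL` to select it by
#'   cross-validation from `lam_grid`.
#' @param lam_grid candidate multipliers of the within-class scatter scale
#'   (mean diagonal of S_w over informative relations); the default grid is
#'   `c(1e-3, 1e-2, 1e-1, 1, 10)`.
#' @param cv_folds folds for stratified cross-validation (>= 2).
#' @param seed integer seed for fold assignment and permutations.
#' @return list of class `rlda_config`.
#' @export
rlda_config <- function(lam = NULL, lam_grid = c(1e-3, 1e-2, 1e-1, 1, 10),
                        cv_folds = 5L, seed = 0L) {
  stopifnot(is.null(lam) || (is.numeric(lam) && lam >= 0),
            length(lam_grid) >= 1L, all(lam_grid >= 0), cv_folds >= 2L)
  structure(list(lam = lam, lam_grid = as.numeric(lam_grid),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "rlda_config")
}

as_contrast_matrix <- function(m) {
  if (inherits(m, "atl_contrast")) {
    list(X = m$X, y = m$y, class_names = m$class_names, space = m$space)
  } else if (is.list(m) && !is.null(m$X) && !is.null(m$y)) {
    y <- factor(m$y)
    if (nlevels(y) != 2L) stop("y must have exactly two levels")
    list(X = as.matrix(m$X), y = y,
         class_names = if (is.null(m$class_names)) levels(y) else m$class_names,
         space = m$space)
  } else {
    stop("m must be an atl_contrast or a list with X and y")
  }
}

#' Class means and within-class scatter
#'
#' @param X numeric matrix (sentences x relations).
#' @param y two-level factor.
#' @return list with `mean_1`, `mean_2`, `within_scatter` (the sample
#'   within-class scatter matrix, sum of squared deviations from the class
#'   means), `n_1`, `n_2`.
#' @export
scatter_stats <- function(X, y) {
  y <- factor(y)
  stopifnot(nlevels(y) == 2L)
  i1 <- y == levels(y)[1]
  n1 <- sum(i1); n2 <- sum(!i1)
  if (n1 == 0 || n2 == 0) stop("both classes must be non-empty")
  mu1 <- colMeans(X[i1, , drop = FALSE])
  mu2 <- colMeans(X[!i1, , drop = FALSE])
  Xc <- X
  Xc[i1, ] <- sweep(X[i1, , drop = FALSE], 2, mu1)
  Xc[!i1, ] <- sweep(X[!i1, , drop = FALSE], 2, mu2)
  list(mean_1 = mu1, mean_2 = mu2, within_scatter = crossprod(Xc),
       n_1 = n1, n_2 = n2)
}

# Centered-within-class matrix and active column set. Columns whose
# within-class deviations are identically zero decouple in (S_w + lam I):
# their scatter row/column is zero, so the solve restricted to the active
# block plus the closed form w_j = d_j / lam on the inactive block is exact.
center_within <- function(X, y) {
  i1 <- y == levels(y)[1]
  mu1 <- colMeans(X[i1, , drop = FALSE])
  mu2 <- colMeans(X[!i1, , drop = FALSE])
  Xc <- X
  Xc[i1, ] <- sweep(X[i1, , drop = FALSE], 2, mu1)
  Xc[!i1, ] <- sweep(X[!i1, , drop = FALSE], 2, mu2)
  list(Xc = Xc, mu1 = mu1, mu2 = mu2,
       active = colSums(Xc * Xc) > 0, n1 = sum(i1), n2 = sum(!i1))
}

# Scale of the within-class scatter: mean diagonal entry over active
# relations; the lambda grid multiplies this quantity.
scatter_scale <- function(X, y) {
  cw <- center_within(X, y)
  if (!any(cw$active)) return(1)
  mean(colSums(cw$Xc[, cw$active, drop = FALSE]^2))
}

rlda_solve <- function(X, y, lam) {
  cw <- center_within(X, y)
  if (cw$n1 < 2 || cw$n2 < 2) {
    stop("each class needs at least 2 samples for the discriminant fit")
  }
  d <- cw$mu1 - cw$mu2
  p <- ncol(X)
  w <- numeric(p)
  a <- cw$active
  if (any(a)) {
    Xa <- cw$Xc[, a, drop = FALSE]
    Sw <- crossprod(Xa)
    A <- Sw + diag(lam, nrow(Sw))
    w[a] <- solve(A, d[a])
  }
  if (any(!a)) {
    w[!a] <- if (lam > 0) d[!a] / lam else 0
  }
  w
}

#' Regularized LDA discriminant direction
#'
#' Solves `(S_w + lam I) w = mu_1 - mu_2` for the discriminant direction
#' `w`; the regularizer keeps the system well-posed when the number of
#' sentences is small relative to the number of relations. Weights are
#' normalized by the largest absolute weight, so the most discriminative
#' relation scores 1 and irrelevant relations score near 0.
#'
#' @param m an `atl_contrast` (or list with `X`, `y`).
#' @param cfg an [rlda_config()]; `cfg$lam` is used if set, otherwise it is
#'   chosen by [select_lambda()].
#' @return list of class `rlda_result`: `direction`, `normalized_weights`,
#'   `ranking` (indices sorted by normalized weight, ties broken by feature
#'   order), `lam`.
#' @export
rlda_direction <- function(m, cfg = rlda_config()) {
  mc <- as_contrast_matrix(m)
  lam <- cfg$lam
  if (is.null(lam)) lam <- select_lambda(m, cfg)$lam
  w <- rlda_solve(mc$X, mc$y, lam)
  mw <- max(abs(w))
  if (mw == 0) {
    warning("all-zero mean difference: zero discriminant direction")
    nw <- numeric(length(w))
  } else {
    nw <- abs(w) / mw
  }
  structure(list(direction = w, normalized_weights = nw,
                 ranking = order(-nw, seq_along(nw)), lam = lam),
            class = "rlda_result")
}

#' Nearest-mean classification
#'
#' Assigns the class of the nearest class mean in Euclidean distance;
#' exact ties go to class 1.
#'
#' @param x numeric vector (one projected sample) or matrix (samples in
#'   rows).
#' @param z1,z2 class means in the same space.
#' @return integer vector of 1s and 2s.
#' @export
nearest_mean_classify <- function(x, z1, z2) {
  if (is.matrix(x)) {
    d1 <- colSums((t(x) - z1)^2)
    d2 <- colSums((t(x) - z2)^2)
  } else {
    d1 <- sum((x - z1)^2)
    d2 <- sum((x - z2)^2)
  }
  ifelse(d1 <= d2, 1L, 2L)
}

stratified_folds <- function(y, k, seed) {
  if (k > min(table(y))) {
    stop("cv_folds (", k, ") exceeds the smallest class size (",
         min(table(y)), ")")
  }
  fold <- integer(length(y))
  rng <- local_rng(seed)
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

local_rng <- function(seed) {
  set.seed(seed)
  invisible(NULL)
}

cv_accuracy <- function(X, y, lam, fold) {
  k <- max(fold)
  correct <- logical(length(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L || min(table(y[tr])) < 2L) {
      stop("cross-validation fold leaves a class with fewer than 2 samples")
    }
    w <- rlda_solve(X[tr, , drop = FALSE], y[tr], lam)
    z <- as.numeric(X %*% w)
    z1 <- mean(z[tr & y == levels(y)[1]])
    z2 <- mean(z[tr & y == levels(y)[2]])
    pred <- nearest_mean_classify(matrix(z[!tr], ncol = 1), z1, z2)
    correct[!tr] <- pred == as.integer(y[!tr])
  }
  mean(correct)
}

#' Select the regularization strength by cross-validation
#'
#' Stratified k-fold cross-validation over the candidate grid
#' (`cfg$lam_grid` times the within-class scatter scale); the value
#' maximizing mean held-out nearest-mean accuracy wins, with ties broken
#' towards the smallest value.
#'
#' @param m an `atl_contrast`.
#' @param cfg an [rlda_config()].
#' @return list with `lam` (chosen value), `grid`, `accuracy` per grid
#'   value.
#' @export
select_lambda <- function(m, cfg = rlda_config()) {
  mc <- as_contrast_matrix(m)
  grid <- sort(cfg$lam_grid * scatter_scale(mc$X, mc$y))
  fold <- stratified_folds(mc$y, cfg$cv_folds, cfg$seed)
  acc <- vapply(grid, function(lam) cv_accuracy(mc$X, mc$y, lam, fold),
                numeric(1))
  list(lam = grid[which.max(acc)], grid = grid, accuracy = acc)
}

#' Select the boundary tolerance by cross-validation
#'
#' Re-featurizes the corpus at each candidate tolerance and scores each by
#' stratified cross-validated nearest-mean accuracy on the given contrast;
#' ties go to the smallest tolerance. The default grid is 0 to 5 frames at
#' 30 frames per second.
#'
#' @param corpus an [atl_corpus()].
#' @param type,target contrast specification as in [make_contrast()].
#' @param eps_grid candidate tolerances in seconds.
#' @param cfg an [rlda_config()]; `cfg$lam` (or a per-tolerance selection
#'   when `NULL`) is used inside the scoring.
#' @param space feature space to use.
#' @param adjacent_only passed to featurization.
#' @return list with `epsilon` (chosen), `grid`, `accuracy`.
#' @export
select_epsilon <- function(corpus, type, target,
                           eps_grid = c(0, 1, 2, 3, 5) / 30,
                           cfg = rlda_config(), space = build_feature_space(),
                           adjacent_only = FALSE) {
  eps_grid <- sort(eps_grid)
  acc <- vapply(eps_grid, function(eps) {
    feats <- featurize_corpus(corpus, space, epsilon = eps,
                              adjacent_only = adjacent_only)
    m <- make_contrast(feats, type, target)
    lam <- cfg$lam
    if (is.null(lam)) lam <- select_lambda(m, cfg)$lam
    fold <- stratified_folds(m$y, cfg$cv_folds, cfg$seed)
    cv_accuracy(m$X, m$y, lam, fold)
  }, numeric(1))
  list(epsilon = eps_grid[which.max(acc)], grid = eps_grid, accuracy = acc)
}

#' Leave-one-sentence-out evaluation
#'
#' Each sentence is classified by a nearest-mean classifier on the
#' discriminant projection fitted to all remaining sentences. With a fixed
#' `cfg$lam` the per-fold direction is obtained exactly by a
#' Sherman-Morrison rank-one downdate of the full-data `(S_w + lam I)`
#' inverse, making the n-fold loop cheap; with `cfg$lam = NULL` the
#' regularizer is re-selected inside every training fold (nested
#' cross-validation), which is slower but never lets the held-out sentence
#' influence the tuning.
#'
#' @param m an `atl_contrast`.
#' @param cfg an [rlda_config()].
#' @return list of class `loso_result`: `accuracy` (mean over iterations),
#'   `weights` (elementwise mean of the per-iteration normalized weight
#'   vectors), `n_iter`, `predictions`, `correct`, `skipped`.
#' @export
loso_evaluate <- function(m, cfg = rlda_config()) {
  mc <- as_contrast_matrix(m)
  X <- mc$X; y <- mc$y
  n <- nrow(X)
  if (n < 4L) stop("leave-one-out evaluation needs at least 4 sentences")
  if (any(table(y) < 2L)) {
    stop("each class needs at least 2 samples")
  }
  if (!is.null(cfg$lam) && cfg$lam > 0) {
    res <- loso_fast(X, y, cfg$lam)
  } else {
    res <- loso_nested(X, y, cfg)
  }
  structure(res, class = "loso_result")
}

loso_fast <- function(X, y, lam) {
  n <- nrow(X); p <- ncol(X)
  cw <- center_within(X, y)
  a <- cw$active
  Xa <- X[, a, drop = FALSE]
  Xca <- cw$Xc[, a, drop = FALSE]
  mu <- rbind(cw$mu1[a], cw$mu2[a])
  ns <- c(cw$n1, cw$n2)
  Sw <- crossprod(Xca)
  Ainv <- chol2inv(chol(Sw + diag(lam, nrow(Sw))))
  d_in <- cw$mu1[!a] - cw$mu2[!a]      # inactive block: w = d / lam
  w_in <- d_in / lam
  yi <- as.integer(y)
  pred <- integer(n)
  sum_nw <- numeric(p)
  skipped <- logical(n)
  for (i in seq_len(n)) {
    c_i <- yi[i]
    nc <- ns[c_i]
    if (nc == 1L) {
      skipped[i] <- TRUE
      next
    }
    x <- Xa[i, ]
    u <- x - mu[c_i, ]
    alpha <- nc / (nc - 1)
    mu_c <- (nc * mu[c_i, ] - x) / (nc - 1)
    mu1i <- if (c_i == 1L) mu_c else mu[1, ]
    mu2i <- if (c_i == 2L) mu_c else mu[2, ]
    d <- mu1i - mu2i
    g <- Ainv %*% d
    v <- Ainv %*% u
    denom <- 1 - alpha * sum(u * v)
    w <- g + v * (alpha * sum(u * g) / denom)
    z1 <- sum(mu1i * w) + sum(cw$mu1[!a] * w_in)
    z2 <- sum(mu2i * w) + sum(cw$mu2[!a] * w_in)
    z <- sum(x * w) + sum(X[i, !a] * w_in)
    pred[i] <- nearest_mean_classify(z, z1, z2)
    wa_full <- numeric(p)
    wa_full[a] <- w
    wa_full[!a] <- w_in
    mw <- max(abs(wa_full))
    if (mw > 0) sum_nw <- sum_nw + abs(wa_full) / mw
  }
  keep <- !skipped
  if (any(skipped)) {
    warning(sum(skipped), " LOSO iteration(s) skipped: training fold lost ",
            "a whole class")
  }
  list(accuracy = mean(pred[keep] == yi[keep]),
       weights = sum_nw / sum(keep), n_iter = sum(keep),
       predictions = ifelse(keep, pred, NA_integer_),
       correct = ifelse(keep, pred == yi, NA), skipped = skipped)
}

loso_nested <- function(X, y, cfg) {
  n <- nrow(X); p <- ncol(X)
  yi <- as.integer(y)
  pred <- integer(n)
  sum_nw <- numeric(p)
  skipped <- logical(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ytr <- y[tr]
    if (length(unique(ytr)) < 2L) {
      skipped[i] <- TRUE
      next
    }
    mtr <- list(X = X[tr, , drop = FALSE], y = ytr)
    lam <- cfg$lam
    if (is.null(lam)) lam <- select_lambda(mtr, cfg)$lam
    w <- rlda_solve(mtr$X, droplevels(ytr), lam)
    z <- as.numeric(X %*% w)
    z1 <- mean(z[tr][ytr == levels(y)[1]])
    z2 <- mean(z[tr][ytr == levels(y)[2]])
    pred[i] <- nearest_mean_classify(z[i], z1, z2)
    mw <- max(abs(w))
    if (mw > 0) sum_nw <- sum_nw + abs(w) / mw
  }
  keep <- !skipped
  if (any(skipped)) {
    warning(sum(skipped), " LOSO iteration(s) skipped: training fold lost ",
            "a whole class")
  }
  list(accuracy = mean(pred[keep] == yi[keep]),
       weights = sum_nw / sum(keep), n_iter = sum(keep),
       predictions = ifelse(keep, pred, NA_integer_),
       correct = ifelse(keep, pred == yi, NA), skipped = skipped)
}

#' Per-class activation rates of a relation
#'
#' Activation characterizes how often a nonmanual relation is employed in
#' each class: the percentage of sentences with at least one instance.
#'
#' @param m an `atl_contrast`.
#' @param j relation index (may be a vector).
#' @return matrix with columns `class1`, `class2` (percentages in
#'   \[0, 100\]).
#' @export
activation_rates <- function(m, j) {
  mc <- as_contrast_matrix(m)
  i1 <- mc$y == levels(mc$y)[1]
  cbind(class1 = 100 * colMeans(mc$X[i1, j, drop = FALSE] >= 1),
        class2 = 100 * colMeans(mc$X[!i1, j, drop = FALSE] >= 1))
}

#' One-dimensional classification accuracy of a single relation
#'
#' Projects every sentence onto the count of relation `j` and classifies
#' with the one-dimensional reduction of the discriminant: the threshold is
#' the midpoint of the two class means (equal priors), sentences on class
#' 1's side of it count as class 1. Reports the percentage of class-1
#' sentences on class 1's side and of class-2 sentences on the other side.
#' A relation absent from class 1 but present in class 2 classifies class 1
#' at 100 percent by absence.
#'
#' @param m an `atl_contrast`.
#' @param j relation index (scalar).
#' @return named numeric `c(class1, class2)` percentages.
#' @export
per_feature_classification <- function(m, j) {
  mc <- as_contrast_matrix(m)
  x <- mc$X[, j]
  i1 <- mc$y == levels(mc$y)[1]
  m1 <- mean(x[i1]); m2 <- mean(x[!i1])
  if (m1 == m2 && stats::var(x) == 0) {
    warning("relation ", j, " is constant with equal class means; ",
            "assigning every sentence to the majority class")
    maj <- if (sum(i1) >= sum(!i1)) 1L else 2L
    return(c(class1 = if (maj == 1L) 100 else 0,
             class2 = if (maj == 2L) 100 else 0))
  }
  pred <- nearest_mean_classify(matrix(x, ncol = 1), m1, m2)
  c(class1 = 100 * mean(pred[i1] == 1L),
    class2 = 100 * mean(pred[!i1] == 2L))
}

#' d-prime sensitivity of a single relation
#'
#' Standardized distance between the two class distributions of the
#' relation count: `|m1 - m2| / sqrt((v1 + v2) / 2)` with unbiased
#' variances. A zero-variance relation with distinct means returns `Inf`
#' (the relation separates the classes perfectly on its own); zero means
#' and zero variance return 0.
#'
#' @param m an `atl_contrast`.
#' @param j relation index (may be a vector).
#' @return numeric vector of sensitivities.
#' @export
dprime <- function(m, j) {
  mc <- as_contrast_matrix(m)
  i1 <- mc$y == levels(mc$y)[1]
  vapply(j, function(jj) {
    x1 <- mc$X[i1, jj]; x2 <- mc$X[!i1, jj]
    num <- abs(mean(x1) - mean(x2))
    den <- sqrt((stats::var(x1) + stats::var(x2)) / 2)
    if (den == 0) {
      if (num == 0) 0 else Inf
    } else {
      num / den
    }
  }, numeric(1))
}

#' Label-permutation significance of the LOSO accuracy
#'
#' Compares the observed leave-one-out accuracy with the null distribution
#' obtained by rerunning the full evaluation under random permutations of
#' the class labels. Reports the empirical p-value
#' `(1 + #\{null >= observed\}) / (1 + reps)` and, for comparability with
#' normal-theory practice, a one-sided one-sample t-test of the null
#' accuracies against the observed value. The regularizer is selected once
#' on the observed labels and held fixed across permutations.
#'
#' @param m an `atl_contrast`.
#' @param cfg an [rlda_config()]; `cfg$seed` drives the permutations.
#' @param reps number of label permutations (>= 19).
#' @return list of class `permutation_result`: `observed_accuracy`,
#'   `null_accuracies`, `p_empirical`, `p_ttest`, `reps`, `seed`, `lam`.
#' @export
permutation_test <- function(m, cfg = rlda_config(), reps = 99L) {
  stopifnot(reps >= 19L)
  mc <- as_contrast_matrix(m)
  lam <- cfg$lam
  if (is.null(lam)) lam <- select_lambda(m, cfg)$lam
  cfg_fix <- rlda_config(lam = lam, lam_grid = cfg$lam_grid,
                         cv_folds = cfg$cv_folds, seed = cfg$seed)
  observed <- loso_evaluate(m, cfg_fix)$accuracy
  null_acc <- numeric(reps)
  local_rng(cfg$seed)
  perms <- replicate(reps, sample(length(mc$y)), simplify = FALSE)
  for (r in seq_len(reps)) {
    mp <- list(X = mc$X, y = mc$y[perms[[r]]])
    null_acc[r] <- loso_evaluate(mp, cfg_fix)$accuracy
  }
  p_emp <- (1 + sum(null_acc >= observed)) / (1 + reps)
  p_t <- if (stats::sd(null_acc) == 0) {
    if (mean(null_acc) < observed) 0 else 1
  } else {
    stats::t.test(null_acc, mu = observed, alternative = "less")$p.value
  }
  structure(list(observed_accuracy = observed, null_accuracies = null_acc,
                 p_empirical = p_emp, p_ttest = p_t, reps = as.integer(reps),
                 seed = cfg$seed, lam = lam),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("<permutation_result> observed accuracy %.3f, ",
                     "null mean %.3f (%d perms), p_emp = %.4g, p_t = %.4g\n"),
              x$observed_accuracy, mean(x$null_accuracies), x$reps,
              x$p_empirical, x$p_ttest))
  invisible(x)
}
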