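test_that("RLDA obeys the scalar closed form and the large-lambda limit", {
  # single feature, class means 2 and 0, within-scatter s: w = 2 / (s + lam)
  x1 <- c(1.5, 2.0, 2.5)   # mean 2
  x2 <- c(-0.5, 0, 0.5)    # mean 0
  X <- matrix(c(x1, x2), ncol = 1)
  y <- factor(rep(c("class1", "class2"), each = 3))
  s_w <- sum((x1 - 2)^2) + sum(x2^2)
  for (lam in c(0.1, 1, 10)) {
    fit <- rlda_direction(list(X = X, y = y), rlda_config(lam = lam))
    expect_equal(fit$direction, 2 / (s_w + lam), tolerance = 1e-12)
  }

  # very large lambda: direction proportional to the mean difference
  gc <- gaussian_contrast(20, 6, delta = 2, seed = 3, k_shift = 2)
  st <- scatter_stats(gc$X, gc$y)
  d <- st$mean_1 - st$mean_2
  fit <- rlda_direction(gc, rlda_config(lam = 1e8))
  cosine <- sum(fit$direction * d) /
    sqrt(sum(fit$direction^2) * sum(d^2))
  expect_gt(cosine, 0.999)
})

test_that("RLDA matches the dense-inverse oracle on random problems", {
  for (seed in 1:10) {
    gc <- gaussian_contrast(20, 10, delta = 1, seed = seed)
    lam <- 0.5
    w <- rlda_direction(gc, rlda_config(lam = lam))$direction
    w0 <- bf_rlda(gc$X, gc$y, lam)
    expect_lt(max(abs(w - w0)) / max(abs(w0)), 1e-8)
  }
})

test_that("RLDA converges to classical LDA as lambda vanishes", {
  skip_if_not_installed("MASS")
  for (seed in 1:5) {
    gc <- gaussian_contrast(40, 8, delta = 1, seed = seed)  # n >> p
    st <- scatter_stats(gc$X, gc$y)
    w0 <- MASS::ginv(st$within_scatter) %*% (st$mean_1 - st$mean_2)
    w <- rlda_direction(gc, rlda_config(lam = 1e-10))$direction
    expect_lt(sqrt(sum((w - w0)^2)) / sqrt(sum(w0^2)), 1e-6)
  }
})

test_that("normalized weights peak at 1 and ranking breaks ties by order", {
  gc <- gaussian_contrast(15, 5, delta = 3, seed = 9)
  fit <- rlda_direction(gc, rlda_config(lam = 1))
  expect_equal(max(fit$normalized_weights), 1)
  expect_setequal(fit$ranking, 1:5)
  # an all-zero mean difference yields a zero direction with a warning
  X <- rbind(diag(4), diag(4))
  y <- factor(rep(c("class1", "class2"), each = 4))
  expect_warning(z <- rlda_direction(list(X = X, y = y),
                                     rlda_config(lam = 1)),
                 "zero")
  expect_equal(z$normalized_weights, rep(0, 4))
  expect_equal(z$ranking, 1:4)
})

test_that("nearest-mean classification picks the closer mean, ties to class 1", {
  expect_equal(nearest_mean_classify(0, 0, 5), 1L)
  expect_equal(nearest_mean_classify(2.5, 0, 5), 1L)   # exact tie
  expect_equal(nearest_mean_classify(4, 0, 5), 2L)
  set.seed(21)
  for (i in 1:100) {
    x <- rnorm(3); z1 <- rnorm(3); z2 <- rnorm(3)
    want <- if (sum((x - z1)^2) <= sum((x - z2)^2)) 1L else 2L
    expect_equal(nearest_mean_classify(x, z1, z2), want)
  }
})

test_that("lambda selection respects the grid and the tie-break rule", {
  gc <- gaussian_contrast(20, 4, delta = 8, seed = 2, k_shift = 2)  # well separated
  one <- select_lambda(gc, rlda_config(lam_grid = 3, cv_folds = 4))
  expect_equal(one$lam, 3 * atldisc:::scatter_scale(gc$X, factor(gc$y)))
  sel <- select_lambda(gc, rlda_config(cv_folds = 4))
  # every lambda attains 100%: smallest grid value wins
  expect_equal(sel$lam, min(sel$grid))
  expect_true(all(sel$accuracy == 1))
  expect_error(select_lambda(gc, rlda_config(cv_folds = 50)),
               "smallest class")
})

test_that("LOSO is perfect on point-mass classes and runs n iterations", {
  X <- rbind(matrix(rep(c(5, 0), each = 6), 6, 2),
             matrix(rep(c(0, 5), each = 6), 6, 2))
  X <- X + matrix(rnorm(24, sd = 0.01), 12, 2)
  y <- factor(rep(c("class1", "class2"), each = 6))
  res <- loso_evaluate(list(X = X, y = y), rlda_config(lam = 0.5))
  expect_equal(res$accuracy, 1)
  expect_equal(res$n_iter, 12L)
  expect_equal(sum(!is.na(res$predictions)), 12L)
})

test_that("fast LOSO downdate equals direct per-fold refits exactly", {
  set.seed(42)
  n <- 30; p <- 10
  X <- matrix(rpois(n * p, 1.2), n, p)
  X[, 4] <- 3L   # constant column exercises the decoupled block
  y <- factor(rep(c("class1", "class2"), each = 15))
  X[y == "class1", 1] <- X[y == "class1", 1] + rpois(15, 2)
  for (lam in c(0.3, 2)) {
    fast <- atldisc:::loso_fast(X, y, lam)
    slow <- atldisc:::loso_nested(X, y, rlda_config(lam = lam))
    expect_equal(fast$accuracy, slow$accuracy)
    expect_identical(fast$predictions, slow$predictions)
    expect_equal(fast$weights, slow$weights, tolerance = 1e-10)
  }
})

test_that("LOSO on shuffled labels stays at chance", {
  gc <- gaussian_contrast(30, 5, delta = 3, seed = 8)
  set.seed(99)
  y_shuf <- sample(gc$y)
  res <- loso_evaluate(list(X = gc$X, y = y_shuf), rlda_config(lam = 1))
  maj <- max(table(y_shuf)) / length(y_shuf)
  sigma <- sqrt(maj * (1 - maj) / length(y_shuf))
  expect_lt(abs(res$accuracy - maj), 3 * sigma + 1e-9)
})

test_that("activation rates report per-class presence percentages", {
  X <- cbind(c(1, 2, 1, 0, 0, 0), c(0, 0, 0, 0, 0, 0))
  y <- factor(rep(c("class1", "class2"), each = 3))
  a <- activation_rates(list(X = X, y = y), 1:2)
  expect_equal(a[1, ], c(class1 = 100, class2 = 0))
  expect_equal(a[2, ], c(class1 = 0, class2 = 0))
})

test_that("planted activation is recovered within the exact binomial interval", {
  g1 <- class_grammar("assertion:positive",
                      list(grammar_rule("span", "brows_up", prob = 0.9)),
                      background = list())
  g2 <- class_grammar("wh_question:positive", list(), background = list(
    grammar_rule("event", "blink", prob = 0.5)))
  co <- suppressWarnings(generate_corpus(
    gen_config(construction_counts = c(assertion = 500L, wh_question = 50L),
               pos_fraction = 1, seed = 12),
    list("assertion:positive" = g1, "wh_question:positive" = g2)))
  fe <- featurize_corpus(co, small_space())
  m <- make_contrast(fe, "construction", "assertion")
  j <- atldisc:::space_lookup(fe$space, "brows_up", "equals", "brows_up")
  act <- activation_rates(m, j)[1, "class1"]
  ci <- qbinom(c(0.005, 0.995), 500, 0.9) / 500 * 100
  expect_gte(act, ci[1])
  expect_lte(act, ci[2])
})

test_that("single-relation classification handles separation, absence and scale", {
  # perfect separation: both sides 100
  X <- cbind(c(2, 1, 3, 0, 0, 0))
  y <- factor(rep(c("class1", "class2"), each = 3))
  expect_equal(per_feature_classification(list(X = X, y = y), 1),
               c(class1 = 100, class2 = 100))
  # absence in class 1 with presence in class 2: class 1 at 100 by absence
  X2 <- cbind(c(0, 0, 0, 0, 2, 0))
  pc <- per_feature_classification(list(X = X2, y = y), 1)
  expect_equal(pc[["class1"]], 100)
  expect_lt(pc[["class2"]], 100)
  # constant feature: majority side with a warning
  X3 <- cbind(rep(1, 6))
  expect_warning(pc3 <- per_feature_classification(list(X = X3, y = y), 1),
                 "majority")
  expect_equal(sum(pc3), 100)
  # scale equivariance
  gc <- gaussian_contrast(25, 3, delta = 1.2, seed = 4)
  base <- per_feature_classification(gc, 1)
  gc$X[, 1] <- gc$X[, 1] * 7.3
  expect_equal(per_feature_classification(gc, 1), base)
})

test_that("identically distributed classes classify near 50 percent", {
  set.seed(10)
  X <- matrix(rnorm(800), 400, 2)
  y <- factor(rep(c("class1", "class2"), each = 200))
  pc <- per_feature_classification(list(X = X, y = y), 1)
  sigma <- 100 * sqrt(0.25 / 200)
  expect_lt(abs(pc[["class1"]] - 50), 3 * sigma)
  expect_lt(abs(pc[["class2"]] - 50), 3 * sigma)
})

test_that("d-prime follows its closed form with degenerate sentinels", {
  y <- factor(rep(c("class1", "class2"), each = 4))
  # equal means -> 0
  X <- cbind(c(1, 2, 3, 4, 4, 3, 2, 1))
  expect_equal(dprime(list(X = X, y = y), 1), 0)
  # means 0 and 1, unit variances -> 1 (unit-variance sample by construction)
  a <- c(-1.5, -0.5, 0.5, 1.5)
  a <- a / sd(a)
  X2 <- cbind(c(a, a + 1))
  expect_equal(dprime(list(X = X2, y = y), 1), 1, tolerance = 1e-6)
  # zero variance, distinct means -> infinity sentinel
  X3 <- cbind(rep(c(0, 2), each = 4))
  expect_equal(dprime(list(X = X3, y = y), 1), Inf)
  # zero variance, equal means -> 0
  X4 <- cbind(rep(1, 8))
  expect_equal(dprime(list(X = X4, y = y), 1), 0)
})

test_that("permutation test flags a strong planted signal and is reproducible", {
  gc <- gaussian_contrast(15, 4, delta = 5, seed = 6)
  cfg <- rlda_config(lam = 1, seed = 7)
  pt <- permutation_test(gc, cfg, reps = 99)
  expect_equal(pt$p_empirical, 1 / 100)
  expect_lt(pt$p_ttest, 1e-6)
  expect_equal(length(pt$null_accuracies), 99L)
  pt2 <- permutation_test(gc, cfg, reps = 99)
  expect_identical(pt$null_accuracies, pt2$null_accuracies)
  expect_identical(pt$observed_accuracy, pt2$observed_accuracy)
})

test_that("tolerance selection re-featurizes per candidate and breaks ties low", {
  g1 <- class_grammar("assertion:positive",
                      list(grammar_rule("meets", "brows_up", "blink",
                                        prob = 0.95)))
  g2 <- class_grammar("wh_question:positive",
                      list(grammar_rule("before", "brows_up", "blink",
                                        prob = 0.95)))
  co <- suppressWarnings(generate_corpus(
    gen_config(construction_counts = c(assertion = 25L, wh_question = 25L),
               pos_fraction = 1, seed = 5),
    list("assertion:positive" = g1, "wh_question:positive" = g2)))
  sel <- select_epsilon(co, "construction", "assertion",
                        eps_grid = c(0.033, 0.067),
                        cfg = rlda_config(lam = 1, cv_folds = 3),
                        space = small_space())
  expect_true(sel$epsilon %in% c(0.033, 0.067))
  expect_equal(length(sel$accuracy), 2L)
  # a one-point grid returns that point
  sel1 <- select_epsilon(co, "construction", "assertion", eps_grid = 0.067,
                         cfg = rlda_config(lam = 1, cv_folds = 3),
                         space = small_space())
  expect_equal(sel1$epsilon, 0.067)
})
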