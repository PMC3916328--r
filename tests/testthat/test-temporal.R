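test_that("classifier reproduces the canonical proposition examples", {
  expect_equal(classify_pair(c(0, 2), c(5, 7), 0.1)$proposition, "before")
  expect_equal(classify_pair(c(0, 2), c(2.05, 4), 0.1)$proposition, "meets")
  expect_equal(classify_pair(c(0, 2), c(2, 4), 0)$proposition, "meets")
  expect_equal(classify_pair(c(1, 3), c(1, 3), 0)$proposition, "equals")
  expect_equal(classify_pair(c(1, 3), c(1, 3), 1)$proposition, "equals")
  expect_equal(classify_pair(c(0, 1), c(0, 3), 0.1)$proposition, "starts")
  expect_equal(classify_pair(c(2, 3), c(0, 3), 0.1)$proposition, "finishes")
  expect_equal(classify_pair(c(1, 2), c(0, 4), 0.1)$proposition, "during")
  expect_equal(classify_pair(c(0, 2), c(1, 4), 0.1)$proposition, "overlaps")
  expect_error(classify_pair(c(1, 1), c(0, 2), 0.1), "positive duration")
})

test_that("classifier emits role order per proposition convention", {
  # finishes: later-starting interval plays the first role
  cl <- classify_pair(c(0, 3), c(2, 3), 0.1)
  expect_equal(cl$proposition, "finishes")
  expect_equal(cl$roles, c(2L, 1L))
  # during: contained interval first
  cl <- classify_pair(c(0, 4), c(1, 2), 0.1)
  expect_equal(cl$proposition, "during")
  expect_equal(cl$roles, c(2L, 1L))
  # starts: the interval that ends first plays the first role
  cl <- classify_pair(c(0, 3), c(0, 1), 0.1)
  expect_equal(cl$proposition, "starts")
  expect_equal(cl$roles, c(2L, 1L))
})

test_that("classification is invariant under argument swap", {
  set.seed(11)
  for (i in 1:200) {
    a <- sort(round(runif(2, 0, 6), 2))
    b <- sort(round(runif(2, 0, 6), 2))
    if (a[1] == a[2] || b[1] == b[2]) next
    eps <- sample(c(0, 0.05, 0.3), 1)
    r1 <- classify_pair(a, b, eps)
    r2 <- classify_pair(b, a, eps)
    expect_equal(r1$proposition, r2$proposition)
    # roles refer to the same physical intervals
    ivs1 <- list(a, b)[r1$roles]
    ivs2 <- list(b, a)[r2$roles]
    if (r1$proposition != "equals") expect_equal(ivs1, ivs2)
  }
})

test_that("classifier agrees with the brute-force oracle on a dense grid", {
  ivs <- grid_intervals(0, 4)
  for (eps in c(0, 0.5)) {
    for (a in ivs) for (b in ivs) {
      got <- classify_pair(a, b, eps)
      want <- bf_allen(a, b, eps)
      expect_equal(got$proposition, want$proposition,
                   info = sprintf("a=(%g,%g) b=(%g,%g) eps=%g",
                                  a[1], a[2], b[1], b[2], eps))
      if (want$proposition != "equals") {
        expect_equal(list(a, b)[[got$roles[1]]], want$first)
      }
    }
  }
})

test_that("enlarging the tolerance only coarsens relations, never refines", {
  # before can only become meets; strict nestings only move into the
  # boundary-equality family (equals/starts/finishes)
  allowed <- list(
    before = c("before", "meets"),
    meets = c("meets", "equals", "starts", "finishes"),
    overlaps = c("overlaps", "equals", "starts", "finishes", "meets"),
    during = c("during", "equals", "starts", "finishes"),
    starts = c("starts", "equals"),
    finishes = c("finishes", "equals"),
    equals = "equals")
  ivs <- grid_intervals(0, 5)
  for (a in ivs) for (b in ivs) {
    p_small <- classify_pair(a, b, 0)$proposition
    p_big <- classify_pair(a, b, 1)$proposition
    expect_true(p_big %in% allowed[[p_small]],
                info = sprintf("a=(%g,%g) b=(%g,%g): %s -> %s",
                               a[1], a[2], b[1], b[2], p_small, p_big))
  }
})

test_that("feature space includes unaries and excludes same-group co-temporals", {
  sp <- build_feature_space()
  e <- sp$entries
  # all 17 unary self-equals present
  unary <- e$first == e$second & e$proposition == "equals"
  expect_equal(sum(unary), 17L)
  expect_setequal(e$first[unary], feature_categories()$name)
  # infeasible: co-temporal within one articulator group
  expect_true(is.na(atldisc:::space_lookup(sp, "brows_up", "equals",
                                           "brows_down")))
  expect_true(is.na(atldisc:::space_lookup(sp, "brows_up", "during",
                                           "brows_down")))
  # feasible: sequential relations within a group
  expect_false(is.na(atldisc:::space_lookup(sp, "head_turn_left", "meets",
                                            "head_turn_right")))
  expect_false(is.na(atldisc:::space_lookup(sp, "blink", "before", "blink")))
  # index is a bijection onto the entry positions
  keys <- ls(sp$index)
  expect_equal(length(keys), nrow(e))
  pos <- vapply(keys, function(k) get(k, envir = sp$index), integer(1))
  expect_setequal(pos, seq_len(nrow(e)))
})

test_that("feature space size matches brute-force enumeration on a toy vocabulary", {
  toy <- data.frame(name = c("brows_up", "brows_down", "blink"),
                    group = c("brows", "brows", "blink"),
                    display = c("A", "B", "C"), stringsAsFactors = FALSE)
  sp <- build_feature_space(toy)
  # brute-force: count all (cat, cat, prop) triples passing the rule
  count <- 0L
  grp <- stats::setNames(toy$group, toy$name)
  for (p in propositions()) for (f in toy$name) for (s in toy$name) {
    if (p %in% c("before", "meets")) {
      count <- count + 1L
    } else if (p == "equals") {
      if (f == s) count <- count + 1L           # unary
      else if (grp[f] != grp[s] && match(f, toy$name) < match(s, toy$name))
        count <- count + 1L
    } else {
      if (f != s && grp[f] != grp[s]) count <- count + 1L
    }
  }
  expect_equal(nrow(sp$entries), count)
  # and the closed form for the full vocabulary
  expect_equal(nrow(build_feature_space()$entries),
               17 + 125 + 2 * 289 + 4 * 250)
})

test_that("extract_relations encodes unaries, pairs, and drops infeasibles", {
  sp <- build_feature_space()
  # single event: exactly one self-equals instance
  s1 <- atl_sentence("s1", "g", "assertion", span = c(0, 3),
                     events = data.frame(category = "brows_up",
                                         onset = 0.2, offset = 2))
  inst <- extract_relations(s1, sp)
  expect_equal(nrow(inst), 1L)
  expect_equal(inst$proposition, "equals")
  expect_equal(inst$first, "brows_up")

  # head up during a spanning brow raise
  s2 <- atl_sentence("s2", "g", "assertion", span = c(0, 10),
                     events = data.frame(
                       category = c("brows_up", "head_move_up"),
                       onset = c(0, 2), offset = c(10, 4)))
  inst2 <- extract_relations(s2, sp)
  expect_true(any(inst2$first == "head_move_up" &
                  inst2$proposition == "during" &
                  inst2$second == "brows_up"))

  # same-group co-temporal pair is infeasible and dropped with a warning
  s3 <- atl_sentence("s3", "g", "assertion", span = c(0, 4),
                     events = data.frame(
                       category = c("brows_up", "brows_down"),
                       onset = c(0, 1), offset = c(3, 2)))
  expect_warning(inst3 <- extract_relations(s3, sp, warn_infeasible = TRUE),
                 "infeasible")
  expect_equal(sum(inst3$proposition == "during"), 0L)
  expect_equal(nrow(inst3), 2L)  # the two unaries remain
})

test_that("extraction matches a pairwise brute-force oracle on random sentences", {
  sp <- build_feature_space()
  set.seed(5)
  for (rep in 1:10) {
    co <- random_corpus(1, rep + 100, max_events = 8)
    s <- co$sentences[[1]]
    inst <- extract_relations(s, sp, epsilon = 0.067)
    ev <- s$events
    E <- nrow(ev)
    # oracle: unaries plus every feasible classified pair
    want <- E
    if (E >= 2) {
      for (i in 1:(E - 1)) for (j in (i + 1):E) {
        r <- bf_allen(c(ev$onset[i], ev$offset[i]),
                      c(ev$onset[j], ev$offset[j]), 0.067)
        f <- if (identical(r$first, c(ev$onset[i], ev$offset[i])))
               ev$category[i] else ev$category[j]
        s2 <- if (identical(r$first, c(ev$onset[i], ev$offset[i])))
                ev$category[j] else ev$category[i]
        if (r$proposition == "equals") {
          ord <- order(match(c(f, s2), feature_categories()$name))
          f2 <- c(f, s2)[ord[1]]; s2 <- c(f, s2)[ord[2]]; f <- f2
        }
        if (!is.na(atldisc:::space_lookup(sp, f, r$proposition, s2))) {
          want <- want + 1L
        }
      }
    }
    expect_equal(nrow(inst), want)
    expect_lte(nrow(inst), E + E * (E - 1) / 2)
  }
})

test_that("adjacent-only counting keeps only consecutive same-category pairs", {
  sp <- build_feature_space()
  s <- atl_sentence("s1", "g", "assertion", span = c(0, 10),
                    events = data.frame(category = rep("blink", 3),
                                        onset = c(0, 3, 6),
                                        offset = c(1, 4, 7)))
  all_pairs <- extract_relations(s, sp, epsilon = 0.1)
  adj <- extract_relations(s, sp, epsilon = 0.1, adjacent_only = TRUE)
  expect_equal(sum(all_pairs$proposition == "before"), 3L)  # C(3,2)
  expect_equal(sum(adj$proposition == "before"), 2L)        # consecutive only
  expect_equal(sum(adj$proposition == "equals"), 3L)        # unaries unchanged
})
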