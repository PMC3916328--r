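# Independent oracles and fixture builders used across the suite.

# Brute-force Allen classifier: evaluates every proposition definition as a
# standalone predicate on both role orderings, then applies the precedence
# order. Structurally independent of the package's decision tree.
bf_allen <- function(a, b, eps) {
  preds <- list(
    equals = function(x, y) abs(x[1] - y[1]) <= eps && abs(x[2] - y[2]) <= eps,
    starts = function(x, y) abs(x[1] - y[1]) <= eps && x[2] < y[2] - eps,
    finishes = function(x, y) abs(x[2] - y[2]) <= eps && x[1] > y[1] + eps,
    during = function(x, y) x[1] > y[1] + eps && x[2] < y[2] - eps,
    overlaps = function(x, y) x[1] < y[1] - eps && x[2] > y[1] + eps &&
      x[2] < y[2] - eps,
    meets = function(x, y) abs(y[1] - x[2]) <= eps,
    before = function(x, y) y[1] - x[2] > eps
  )
  for (p in c("equals", "starts", "finishes", "during", "overlaps",
              "meets", "before")) {
    ab <- preds[[p]](a, b)
    ba <- preds[[p]](b, a)
    if (ab && ba) {
      # only possible for symmetric configurations; emit earlier start first
      if (a[1] <= b[1]) return(list(proposition = p, first = a, second = b))
      return(list(proposition = p, first = b, second = a))
    }
    if (ab) return(list(proposition = p, first = a, second = b))
    if (ba) return(list(proposition = p, first = b, second = a))
  }
  NULL
}

# all integer-endpoint intervals with endpoints in [lo, hi]
grid_intervals <- function(lo, hi) {
  out <- list()
  for (s in lo:(hi - 1)) for (e in (s + 1):hi) {
    out[[length(out) + 1L]] <- c(s, e)
  }
  out
}

# Dense RLDA oracle: within-class scatter accumulated sample by sample as
# explicit outer products, then a plain dense solve on the full system.
bf_rlda <- function(X, y, lam) {
  y <- factor(y)
  p <- ncol(X)
  i1 <- y == levels(y)[1]
  mu1 <- colMeans(X[i1, , drop = FALSE])
  mu2 <- colMeans(X[!i1, , drop = FALSE])
  Sw <- matrix(0, p, p)
  for (i in seq_len(nrow(X))) {
    mu <- if (i1[i]) mu1 else mu2
    d <- X[i, ] - mu
    Sw <- Sw + outer(d, d)
  }
  solve(Sw + lam * diag(p), mu1 - mu2)
}

# random millisecond-resolution corpus for round-trip tests
random_corpus <- function(n_sentences, seed, max_events = 6) {
  set.seed(seed)
  cats <- feature_categories()$name
  labs <- sentence_labels()
  sentences <- lapply(seq_len(n_sentences), function(i) {
    constr <- sample(labs$constructions, 1)
    pol <- if (constr == "yes_no_question") "neutral"
           else sample(c("positive", "negative"), 1)
    dur <- round(runif(1, 1, 5), 3)
    k <- sample(0:max_events, 1)
    ev <- if (k == 0) {
      data.frame(category = character(), onset = numeric(),
                 offset = numeric())
    } else {
      on <- round(runif(k, 0, dur - 0.2), 3)
      data.frame(category = sample(cats, k, replace = TRUE),
                 onset = on,
                 offset = pmin(round(on + runif(k, 0.05, 1.5), 3), dur))
    }
    atl_sentence(sprintf("s%03d", i), sprintf("sg%02d", (i %% 4) + 1),
                 constr, pol, span = c(0, dur), events = ev)
  })
  atl_corpus(sentences)
}

# gaussian two-class matrix with a mean shift on the first `k_shift` features
gaussian_contrast <- function(n_per_class, p, delta, seed, k_shift = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  X[seq_len(n_per_class), seq_len(k_shift)] <-
    X[seq_len(n_per_class), seq_len(k_shift)] + delta
  list(X = X, y = factor(rep(c("class1", "class2"), each = n_per_class)))
}

# a minimal EAF document assembled in code
eaf_fixture <- function(path) {
  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<ANNOTATION_DOCUMENT AUTHOR="" FORMAT="3.0" VERSION="3.0">',
    '<TIME_ORDER>',
    '<TIME_SLOT TIME_SLOT_ID="ts1" TIME_VALUE="1000"/>',
    '<TIME_SLOT TIME_SLOT_ID="ts2" TIME_VALUE="3000"/>',
    '<TIME_SLOT TIME_SLOT_ID="ts3" TIME_VALUE="1200"/>',
    '<TIME_SLOT TIME_SLOT_ID="ts4" TIME_VALUE="2800"/>',
    '<TIME_SLOT TIME_SLOT_ID="ts5" TIME_VALUE="4000"/>',
    '<TIME_SLOT TIME_SLOT_ID="ts6" TIME_VALUE="6000"/>',
    '<TIME_SLOT TIME_SLOT_ID="ts7" TIME_VALUE="4500"/>',
    '<TIME_SLOT TIME_SLOT_ID="ts8" TIME_VALUE="5100"/>',
    '</TIME_ORDER>',
    '<TIER TIER_ID="Sentence" PARTICIPANT="signer01">',
    '<ANNOTATION><ALIGNABLE_ANNOTATION ANNOTATION_ID="a1"',
    ' TIME_SLOT_REF1="ts1" TIME_SLOT_REF2="ts2">',
    '<ANNOTATION_VALUE>sent01</ANNOTATION_VALUE>',
    '</ALIGNABLE_ANNOTATION></ANNOTATION>',
    '<ANNOTATION><ALIGNABLE_ANNOTATION ANNOTATION_ID="a2"',
    ' TIME_SLOT_REF1="ts5" TIME_SLOT_REF2="ts6">',
    '<ANNOTATION_VALUE>sent02</ANNOTATION_VALUE>',
    '</ALIGNABLE_ANNOTATION></ANNOTATION>',
    '</TIER>',
    '<TIER TIER_ID="Brows">',
    '<ANNOTATION><ALIGNABLE_ANNOTATION ANNOTATION_ID="a3"',
    ' TIME_SLOT_REF1="ts3" TIME_SLOT_REF2="ts4">',
    '<ANNOTATION_VALUE>up</ANNOTATION_VALUE>',
    '</ALIGNABLE_ANNOTATION></ANNOTATION>',
    '</TIER>',
    '<TIER TIER_ID="Blinks">',
    '<ANNOTATION><ALIGNABLE_ANNOTATION ANNOTATION_ID="a4"',
    ' TIME_SLOT_REF1="ts7" TIME_SLOT_REF2="ts8">',
    '<ANNOTATION_VALUE>blink</ANNOTATION_VALUE>',
    '</ALIGNABLE_ANNOTATION></ANNOTATION>',
    '</TIER>',
    '<TIER TIER_ID="Gloss">',
    '<ANNOTATION><ALIGNABLE_ANNOTATION ANNOTATION_ID="a5"',
    ' TIME_SLOT_REF1="ts3" TIME_SLOT_REF2="ts4">',
    '<ANNOTATION_VALUE>IF</ANNOTATION_VALUE>',
    '</ALIGNABLE_ANNOTATION></ANNOTATION>',
    '</TIER>',
    '</ANNOTATION_DOCUMENT>')
  writeLines(xml, path)
  path
}

# background-only grammars carrying no class information, over a reduced
# three-category vocabulary; used for chance-level and type-I simulations
null_grammars <- function() {
  bg <- list(grammar_rule("event", "brows_up", prob = 0.6),
             grammar_rule("event", "brows_down", prob = 0.5),
             grammar_rule("event", "blink", prob = 0.8),
             grammar_rule("event", "blink", prob = 0.5))
  list("assertion:positive" =
         class_grammar("assertion:positive", list(), background = bg),
       "wh_question:positive" =
         class_grammar("wh_question:positive", list(), background = bg))
}

small_space <- function() build_feature_space(feature_categories()[1:3, ])
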