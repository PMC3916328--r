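---
title: "Discriminant temporal relations in annotated event sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminant temporal relations in annotated event sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atldisc)
```

## The problem

Sign languages mark grammatical constructions — questions, conditionals,
negation — with *nonmanuals*: articulations of the face and head other
than the hands. A brow raise spanning a sentence can mark a Yes/no
question; a fast headshake (one head turn immediately met by the opposite
turn) marks negation. Which articulations, and crucially which *temporal
configurations* of articulations, discriminate one construction from the
others is hard to establish by eye across thousands of annotated videos.

`atldisc` operationalizes this question. Sentences arrive as sets of timed
articulator events drawn from a fixed 17-category vocabulary (brows
up/down; blink; mouth open/closed; mouth shape round/flat/other; teeth
closed/open/touching lip; head turns, tilts and up/down movements, each
left/right or up/down). Categories of one articulator are mutually
exclusive in time. Each sentence carries a construction label
(hypothetical conditional, Yes/no question, Wh-question, postposed
Wh-question, assertion) and a polarity (positive/negative; Yes/no
questions are polarity-neutral), giving nine sentence classes.

## Temporal encoding

Two event intervals stand in exactly one of seven Allen propositions:
*before*, *meets*, *overlaps*, *equals*, *starts*, *during*, *finishes*.
Inverse relations are not separate labels; the classifier emits each pair
in a canonical role order (the contained interval is "during" the
container, the later-starting interval "finishes" the earlier one), which
subsumes them.

Annotated boundaries are noisy: two articulations never abut to the
frame. All boundary-equality comparisons therefore carry a tolerance
ε ≥ 0: boundaries are equal when they differ by at most ε. The default,
ε = 0.067 s, is two frames at 30 fps; `select_epsilon()` can replace it by
stratified cross-validation over a frame-unit grid (0–5 frames). The
decision tree tests, in precedence order on the pair ordered by start:
equals, starts, finishes, during, overlaps, meets, before. Precedence
resolves boundary ambiguity deterministically, and with all branches
expressed through three shared boundary differences the seven cases are
exhaustive for every ε ≥ 0 — the test suite verifies exhaustive agreement
with an independent brute-force implementation of the definitions.
Although the motivating case for ε is *meets*, the same acquisition noise
affects start and end coincidences, so ε applies to every boundary
comparison, not only to gaps.

A single occurrence is encoded as the event *equalling* itself, so unary
markers ("brows move up") and binary relations live in one feature space.
We use seven propositions even though `equals` could be viewed as
redundant with the unary encoding: published discriminant tables contain
both unary rows and binary equals rows, and keeping both needs no change
of algorithm.

The feasible relation space excludes co-temporal triples (overlaps,
equals, starts, during, finishes) whose two categories share an
articulator group — the brows cannot be up and down at once — while
keeping sequential triples within a group (a left turn meeting a right
turn is the headshake signature) and same-category repeats for *before*
and *meets* (multiple blinks, repeated mouth openings). For the full
vocabulary this yields 17 unary + 125 equals + 2 × 289 before/meets +
4 × 250 other co-temporal = 1720 indexed relations; the package computes
this dimension rather than asserting a number.

By default every qualifying event pair is counted, not only temporally
adjacent ones: a sentence with three blinks contributes three
blink-*before*-blink instances. The histogram description ("the number of
times a relation repeats") is ambiguous on this point, so the alternative
is exposed as `adjacent_only`, under which only consecutive same-category
pairs count (two instances for three blinks).

## Discriminant analysis

For a binary contrast (one construction versus the rest with polarity
pooled — Experiment 1 — or positive versus negative within a construction
— Experiment 2), let μ₁, μ₂ be the class means of the count vectors and
S_w the within-class scatter. The discriminant direction solves

  (S_w + λI) w = μ₁ − μ₂.

The regularizer keeps the system well-posed when relations outnumber
sentences. Ranking uses |w| normalized by its maximum, ties broken by
feature order. Columns with zero within-class variance decouple
algebraically from the solve (their scatter rows vanish), so the
implementation solves the active block and uses the closed form
w = d/λ elsewhere; this is an exact reduction, not an approximation.

λ is selected by stratified k-fold cross-validation (default 5 folds)
over the grid {10⁻³, 10⁻², 10⁻¹, 1, 10} × s̄, where s̄ is the mean
diagonal of S_w over informative relations; ties go to the smallest
value. Using a data-scale multiplier keeps the grid meaningful across
corpus sizes.

Evaluation is leave-one-sentence-out: the direction and class means are
fit on n−1 sentences and the held-out sentence is classified by the
nearest class mean on the projection (exact ties to class 1). By default
λ is re-selected inside every training fold, so the held-out sentence
never influences tuning; with a fixed λ the per-fold direction is
obtained by a Sherman–Morrison rank-one downdate of the full-data
(S_w + λI)⁻¹ — exactly equal to refitting, verified in the tests — which
makes the n-fold loop, and permutation testing on top of it, cheap.

Per-relation descriptive statistics mirror published discriminant tables:

* **activation** — percent of each class containing the relation at least
  once (counts feed the discriminant; presence feeds activation, since
  multiplicity matters for markers like repeated headshakes);
* **d′** = |m₁ − m₂| / √((v₁ + v₂)/2) with unbiased variances. The
  pooled form is a choice; a zero-variance relation with distinct means
  returns +∞, matching the non-finite entries seen for relations that
  classify one class perfectly by absence, and 0/0 returns 0;
* **single-relation classification** — the 1-D reduction of the
  discriminant with equal priors, i.e. a threshold at the midpoint of the
  class means on that coordinate; each class's percentage on its own side
  is reported separately, which is why priors are ignored despite
  unbalanced classes. A constant relation with equal means is ill-defined
  and reported as the majority side with a warning.

Significance uses label permutations: the full LOSO evaluation is re-run
under `reps` seeded permutations of the class labels; the empirical
p-value is (1 + #{null ≥ observed})/(1 + reps). A one-sided one-sample
t-test of the null accuracies against the observed value is reported
alongside for comparability with normal-theory practice, though the
empirical p-value is primary (the t-test assumes normality of null
accuracies). λ is selected once on the observed labels and held fixed
across permutations, keeping the null distribution comparable to the
observed statistic.

## The synthetic corpus generator

The original annotated video corpus is not distributed, so the generator
emulates its *structure*: 2,347 sentences (506 conditionals, 350
Wh-questions, 124 postposed Wh-questions, 313 Yes/no questions, 1,054
assertions), 15 signers assigned round-robin with a log-normal
duration effect (sd 0.1), sentence durations Gaussian (3 ± 0.8 s,
truncated at 0.5 s), and all times quantized to milliseconds. The
positive/negative split within each construction is not published; the
generator defaults to 2/3 positive, a typical elicitation balance, and it
is configurable.

Class grammars plant the headline markers at the activation levels the
study reports: a brow raise spanning conditionals (0.891) and Yes/no
questions (0.923); brow lowering spanning Wh-questions (0.894) and
postposed Wh-questions (0.992, either spanning alone or met by a
preceding brow raise, 0.371); a round mouth shape starting or contained
in the lowered brows; a flat mouth shape finishing the Yes/no brow raise
(0.329); and for negative polarity the headshake signature — a head turn
*meeting* the opposite turn at about 0.7 in negatives versus under 0.17
in positives. Shared background rules (blinks, mouth and teeth activity,
non-abutting head turns at rates taken from the published activation
columns, e.g. flat mouth near 0.7, open teeth 0.85) carry no class
information and form the noise floor.

Binary templates place their two intervals with boundary margins of 4ε,
so Gaussian jitter (default sd 0.01 s ≤ ε/3) cannot flip the planted
proposition; planted *meets* gaps are drawn from [0, 0.03] s, inside the
default tolerance. When a rule's second category already has a realized
event (say the spanning brow raise), the first event is placed relative
to it — otherwise the merge of same-category intervals would silently
turn a planted *finishes* into *during*. Same-articulator overlaps
between different categories are physically impossible and are resolved
by trimming the later event. One seeded RNG stream drives a corpus, so a
seed reproduces it byte for byte.

What the generator does *not* emulate: kinematics and co-articulation,
signer-specific marker preferences, lexically driven mouthings, and the
full event inventory of real signing. A consequence of the dependent-rule
design is that anchor categories run a few points above their nominal
activation (rules that fall back to creating their own anchor add
occurrences). Passing end-to-end tests on generated corpora therefore
shows that the pipeline recovers planted temporal structure at realistic
noise levels — not that it would reproduce the published percentages on
the real corpus.

## Numerical and design choices

* Times are seconds internally; EAF milliseconds are divided by 1000 on
  read. The tabular format prints nine decimals, which round-trips
  millisecond-resolution times exactly.
* Overlapping or abutting same-category events are merged (union) at
  load: an articulator excursion is one event, and duplicates are coder
  noise. The merge is order-independent and idempotent.
* Events crossing a sentence boundary are clipped; relations are computed
  strictly within sentences.
* Degenerate inputs: non-positive-duration intervals are hard errors; an
  all-zero mean difference yields a zero direction with a warning; LOSO
  iterations whose training fold loses a whole class are skipped with a
  warning; cross-validation folds exceeding the smallest class size are
  hard errors.
* Nested versus global tuning: whether λ/ε selection belongs inside each
  LOSO fold or once globally is a genuine design fork; the package nests
  by default (`cfg$lam = NULL`) and exposes the global choice by fixing
  `cfg$lam`.
* Report formatting: percentages with one decimal, weights with two,
  matching the precision of published tables.

## Validation problem sizes

The shipped validation suite runs the classifier against a brute-force
oracle exhaustively on integer-endpoint intervals in [0, 6] at
ε ∈ {0, 0.5}; checks the discriminant against a dense-solve oracle on 100
random 10-feature problems and against classical LDA as λ → 0; recovers a
relation planted at 0.9 vs 0.05 activation with 200 sentences per class
over 10 seeds; calibrates the permutation test's type-I error over 200
replicates of 60-sentence null corpora at 99 permutations; checks the
rank agreement of d′ with single-relation accuracy on a 294-sentence
corpus; and reproduces the qualitative top-ranked markers on the full
2,347-sentence emulation. These sizes were chosen to give stable
statistics while keeping the suite comfortably runnable on one CPU.

## Limitations

Only first-order (pairwise) temporal structure is modelled; triples and
longer configurations are out of reach of the feature space. The
discriminant is linear on counts; heavy-tailed count distributions are
not transformed. Multi-class (9-way) joint classification is not
implemented — the design follows the one-vs-all and within-construction
contrasts of the original analyses. EAF support covers alignable
annotations only (no controlled vocabularies or symbolic subdivisions),
and the package does not write EAF.
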