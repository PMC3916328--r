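# atldisc

Discriminant temporal-relation analysis of interval-annotated behavioural
event sequences, built for the study of **nonmanual grammatical markers**
in sign language — the linguistically controlled articulations of the
face and head (brow position, blinks, mouth aperture and shape, teeth
visibility, head turns/tilts/movements) that mark constructions such as
questions, conditionals and negation.

Given sentences annotated with timed articulator events (from ELAN EAF
files or a plain tabular format), the package answers: *which articulator
events, and which temporal configurations of event pairs, discriminate one
sentence class from the rest?*

## Method

1. **Temporal encoding.** Every ordered pair of event intervals is
   classified into one of the seven Allen propositions — *before*, *meets*,
   *overlaps*, *equals*, *starts*, *during*, *finishes* — with a boundary
   tolerance ε (default 0.067 s ≈ 2 frames at 30 fps): two boundaries
   count as equal when they differ by at most ε. Single occurrences are
   encoded as an event *equalling* itself. Relations that are physically
   impossible (co-temporal configurations of two categories of the same
   articulator, e.g. *brows up equals brows down*) are excluded, leaving a
   feasible relation space of 1720 entries for the 17-category vocabulary.
   A sentence becomes a histogram **x** of occurrence counts over this
   space.

2. **Discriminant ranking.** For a binary contrast with class means μ₁, μ₂
   and within-class scatter S_w, regularized linear discriminant analysis
   solves (S_w + λI) **w** = μ₁ − μ₂; λ is chosen by stratified
   cross-validation. Relations are ranked by |w| normalized to its maximum.

3. **Validation.** Leave-one-sentence-out (LOSO) nearest-mean
   classification on the projection gives the contrast's accuracy; each
   top relation is reported with its per-class activation (% of sentences
   containing it), sensitivity d′ = |m₁ − m₂| / √((v₁ + v₂)/2), and
   one-dimensional classification accuracy; label-permutation testing
   gives empirical significance.

A synthetic corpus generator with class-conditional temporal grammars
emulates the study corpus (2,347 sentences, 15 signers, 5 construction
types plus polarity = 9 classes) so the whole pipeline is exercisable
without the original videos.

## Worked example

```r
library(atldisc)

counts <- c(hypothetical_conditional = 63L, wh_question = 44L,
            wh_question_postposed = 16L, yes_no_question = 39L,
            assertion = 132L)
corpus <- generate_corpus(gen_config(construction_counts = counts, seed = 42))
features <- featurize_corpus(corpus, epsilon = 0.067)
contrast <- make_contrast(features, "construction", "yes_no_question")
discriminant_report(contrast, rlda_config(seed = 42), top_k = 5)
```

```
Discriminant relations: yes_no_question vs others (LOSO accuracy 90.1%)
  relation                                weight act1 act2 dprime cls1 cls2
1 Head turns right during brows move up   1.00   66.7 14.1 1.18   66.7 85.9
2 Teeth open during brows move up         0.97   76.9 18.4 1.43   76.9 81.6
3 Blink during brows move up              0.92   79.5 18.0 1.20   79.5 82.0
4 Mouth shape flat finishes brows move up 0.71   28.2 1.6  0.80   28.2 98.4
5 Head turns left                         0.67   61.5 82.7 0.66   38.5 82.7
```

Each row is one temporal relation: its normalized discriminant weight
(1 = most discriminative), its activation in Yes/no questions versus all
other sentences (e.g. "Mouth shape flat finishes brows move up" occurs in
28.2% of Yes/no questions but 1.6% of the rest), its d′, and how well the
relation alone classifies each side. Relations *during*/*finishing* a
spanning brow raise dominating the Yes/no contrast is exactly the
qualitative structure the generator plants.

The same pipeline runs from the shell:

```sh
exec/atldisc simulate --out corpus.tsv --seed 42
exec/atldisc rank --input corpus.tsv --out report.csv \
    --type construction --target yes_no_question --seed 42
exec/atldisc permtest --input corpus.tsv --out perm.json \
    --type construction --target yes_no_question --reps 99
```

Every command writes a `.manifest.json` recording seed, tolerance, λ and
package version, sufficient to reproduce its artifact.

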