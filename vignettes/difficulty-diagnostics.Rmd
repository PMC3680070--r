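---
title: "Instance-level difficulty diagnostics for relation-extraction benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Instance-level difficulty diagnostics for relation-extraction benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppidiag)
```

## The problem

Benchmark comparisons of relation-extraction systems — here, classifiers
that decide whether a sentence asserts an interaction between a pair of
protein mentions (PPI extraction) — are usually reported as corpus-level
precision/recall/F1. Corpus-level scores hide what happens at the instance
level: whether different systems fail on the *same* candidate pairs,
whether hard pairs share linguistic characteristics, and whether combining
dissimilar systems would help. `ppidiag` implements the instance-level
methodology for these questions: every classifier is reduced to a column
of predicted labels over the shared pair universe, and everything else is
derived from that matrix.

Two evaluation settings are treated as parallel prediction tables rather
than training protocols: CV (document-level cross-validation within a
corpus) and CL (cross-learning: train on four corpora, test on the fifth).
In this package they are simply two `prediction_set` objects with separate
rosters; no training happens here.

## Success levels and difficulty classes

The **success level** of a candidate pair is the number of classifiers in
a setting's roster that predict its gold label correctly — an integer in
`0..13` for a 13-classifier CV roster, `0..12` for the CL roster. The
per-corpus histogram of success levels is the raw material for difficulty
stratification:

* the **difficult** set is the non-empty level *prefix* (`s <= t`) whose
  size is closest to 10% of the corpus, ties broken toward the smaller
  set;
* the **easy** set is the smallest non-empty level *suffix* (`s >= t`)
  whose size is at least 10% of the corpus.

The asymmetry is deliberate. Both sides are nominally "the ~10% extremes",
but on the published per-corpus histograms only this pairing reproduces
all twenty printed set sizes: the closest rule reproduces the ten
difficult sizes but two of the easy sizes only under the at-least rule
(success-level distributions are strongly right-heavy, so the topmost
level alone can be far from 10%). Both rules are available on both sides
(`rule =` argument of `cut_difficult()` / `cut_easy()`), and
`difficulty_sets()` flags any side on which the two rules disagree rather
than guessing intent.

Universal classes intersect the two settings: `D = D_CV ∩ D_CL`,
`E = E_CV ∩ E_CL`, everything else neutral (`N`). With gold labels the
signed subclasses ND/PD/NE/PE follow. Whether an overlap between the CV
and CL sets is larger than chance is tested by Pearson's chi-square on the
2x2 membership table without continuity correction; a result counts as
significant when p < 0.001 *and* the observed overlap exceeds the expected
`|A||B|/N` (an enrichment test — depleted overlaps are never flagged). The
reported `p` is the usual two-sided chi-square(1) tail, with a one-sided
half-tail alongside. On universes small enough to enumerate, the one-sided
p tracks the exact hypergeometric (mid-p) tail closely up to the expected
overlap and becomes anti-conservative deeper in the enrichment tail; the
test suite pins down both regimes. For the corpus-scale universes the
method is meant for (hundreds to thousands of pairs) the approximation is
immaterial.

## Expected-correctness bookkeeping

Classifiers differ in how often they predict the positive class (the rate
`r`, in percent, over the pooled pair population of a setting — pooling is
a documented choice, surfaced in report headers). On an all-negative
stratum of size `n`, a classifier that applied its rate blindly would get
`e = round((1 - r/100) * n)` pairs right; on an all-positive stratum,
`e = round((r/100) * n)`. Rounding is half-away-from-zero, which matches
the published worked examples computed from one-decimal rates (a handful
of printed values differ by exactly 1 because the source used unrounded
rates; the tests document this). The ratios `observed/e` and
`observed/size` separate what a classifier achieves on a difficulty
stratum from what its class prior alone would give it.

Multiclass difficulty-prediction reports use one-vs-rest P/R/F per class
and a *support-weighted* total row. Weighted (not micro) averaging is used
because it reproduces the published total row from the published confusion
matrix; micro-averaging does not reproduce the precision total. F with a
zero denominator is defined as 0 throughout.

## Agreement and clustering

Similarity between two classifiers is the fraction of shared pairs with
identical predicted labels — gold labels play no role, and settings are
never mixed. Clustering runs `stats::hclust` on the distance
`1 - agreement` with complete linkage by default (average linkage by
flag); classifiers are sorted by id before clustering so merge ties break
deterministically. `1 - agreement` is not asserted to be metric; only
agglomeration is used. Dendrograms export to Newick with branch lengths
equal to merge-height differences, so a leaf merged at height *h* carries
a branch of length *h*.

## The feature space

Feature extraction works on the blinded token sequence: each entity span
collapses to one token, `ENT1`/`ENT2` for the focus pair and `PROT` for
bystanders. Clue features (interaction, negation, hedge word lists) are
evaluated in four scopes — `s` whole sentence, `b` before the earlier
entity, `w` strictly between, `a` after the later entity — an
interpretation of the published feature table's scope letters documented
as such. Default word lists ship as plain-text files under
`inst/extdata/lexicons/` and are user-overridable; the original study did
not publish its lists.

Parse-layer features use the shortest path between the entity head tokens
(the last token inside the entity span) on the undirected dependency
graph — unit weights, deterministic tie-break by the lexicographically
smallest token-index sequence — and the path through the lowest common
ancestor in the constituency tree. Label distributions (whole graph, whole
tree, both paths) yield occurrence counts, relative frequencies, and
Shannon entropies in bits; an alternative mode computes Kullback-Leibler
divergence from the corpus-wide label background instead of entropy, since
the published feature list names both notions in different places. The
background reference for the KL mode is this package's own choice. Missing
parse layers yield `NA` features plus explicit `has_dg`/`has_st`/
`dg_connected` flags — never silent zeros.

Information gain discretizes continuous features by a supervised binary
split maximizing IG, recursing once (at most four bins) — a simple,
deterministic rule chosen here; the original study names no rule. Signs
come from the point-biserial correlation between the feature and the
binary class indicator. The difficulty model is a CART-style tree (`rpart`
with information splitting, minimum leaf 25, depth cap 12, no pruning) —
stability-oriented defaults, since no hyperparameters were published — and
is evaluated by document-level 10-fold cross-validation with a pooled
confusion matrix by default; resubstitution is available because the
original protocol is not stated. The baseline harness reduces the
published nine-learner menu to five inductive-bias families (decision
tree, naive Bayes, logistic regression, a OneR-style rule, nearest
neighbor) plus a majority-class control, all trained strictly across
document-level fold boundaries with a hard error on fold leakage.

## What the synthetic generator emulates

No corpus or classifier outputs are redistributable here, so the package
carries a seeded generator whose defaults encode the study conditions the
methodology expects:

* five corpora shaped like the standard benchmarks — pair counts
  5834/9666/433/817/330 and gold positive ratios
  17.1/26.2/37.6/41.0/49.7%;
* class-conditional sentence lengths of 27.6 words (sentences in a
  positive context) versus 37.2 (negative), and entity token distances of
  7.15 (positive pairs) versus 9.67 (negative);
* positive-pair odds decaying with protein count and sentence length, so
  the positive rate falls across length bins and mention counts;
* dependency-chain labels drawn from the
  {nsubj, dobj, nn, appos, conj_and, dep, det, amod, prep_with, prep_in,
  nsubjpass} alphabet with class-conditioned frequencies, and shallow
  constituency chunks likewise, so feature analysis has a recoverable
  signal;
* a 13-classifier CV roster in three representation families (syntax
  tree, dependency, shallow), the CL roster dropping the slowest tree
  kernel; per-pair latent difficulty `delta ~ Beta(2, 2)` shared by all
  classifiers; a per-pair per-family error component (`tau = 0.15`,
  coupling 0.7) that makes same-family classifiers agree more; and a flat
  correctness penalty of 0.12 in the CL setting, the midpoint of the
  10-15 point cross-setting F gap the methodology was developed on.

Correctness, not the predicted label, is modeled directly:
`P(correct) = clamp(b_c - lambda_c * delta_p + rho_c * u_family(p)
+/- bias_c * (0.5 + delta_p) - [CL] * penalty, 0.02, 0.98)`. The signed
bias term raises correctness on gold-positive pairs and lowers it on
gold-negative pairs (or vice versa), which is what moves a classifier's
realized positive rate; because `E[0.5 + delta] = 1`, the closed form
`r = bias + g * b_eff + (1-g) * (1-b_eff)` holds exactly and serves as the
test oracle (`positive_bias_for_rate()`, `expected_positive_rate()`). The
difficulty scaling of the bias lets easy positives stay classifiable,
mirroring the near-perfect recall real systems show on easy positive
pairs.

Three deterministic calibrations make the configured quantities exact in
expectation rather than approximate: a global intercept on the pair-odds
logit is solved (by `uniroot`) so the expected gold ratio equals the
target; the two consecutive-entity gap means are solved from a 2x2 linear
system so the pair-level class-conditional distance means land on 7.15 and
9.67 even though non-adjacent pairs' distances are sums of gaps; and two
per-context sentence-length offsets are solved (linearized, one refinement
pass) so the *pair-level* class-conditional length means land on 27.6 and
37.2 despite mention count growing with length (length-biased sampling
would otherwise inflate both means). Protein counts are drawn from a
feasibility-truncated distribution given the sentence length, with
positive contexts tilted toward fewer mentions; crowded draws compress
gaps proportionally rather than stretching the sentence.

Latent difficulty is independent of the text by default, exactly
Beta(2, 2). An optional `difficulty_link = "surface"` mode ranks pairs by
a sentence-feature score (constituent-label entropy and length, plus
noise) and maps ranks through the Beta quantile function, preserving the
marginal while coupling difficulty to observable features — this is the
mode under which feature-analysis recovery is demonstrated.

What the generator does **not** emulate: fluent English (sentences are
template token sequences), real parser errors, annotation-guideline
differences between corpora, document-level topical structure, and
correlation between difficulty and annotation errors. Passing tests on
synthetic data therefore demonstrate that the *pipeline arithmetic and its
statistical machinery* behave as specified under known ground truth — not
that any particular real corpus has these properties.

## Numerical conventions and degenerate inputs

* Presentation rounding is half-away-from-zero (`round_half_away()`);
  base R's half-to-even is never used for reported numbers.
* P, R, F are 0 when their denominators vanish; `observed/e` is `NA` when
  `e = 0`.
* Cutoffs require a non-empty corpus; a single-level histogram yields the
  whole corpus on both sides; closest-rule ties go to the smaller set.
* Majority votes need an odd committee or an explicit tie rule
  (`positive`, `negative`, or `error`).
* Degenerate 2x2 overlap tables (empty set, set equal to universe) are
  errors, not NaNs.
* The unified-format reader converts inclusive `a-b` character offsets to
  0-based half-open spans at the boundary; all internal coordinates are
  half-open, and round-trips are lossless including unknown XML payload.
  Pairs are unordered and self-pairs are rejected at parse time.
* Prediction files carry labels only — the analysis is label-level
  throughout; margins or scores are out of scope.

## Problem sizes used in the checks

The shipped tests exercise the generator at 330-2,500 pairs per corpus
(ten-seed replicate loops where a property is distributional), the full
pipeline at a 0.04 size factor (~680 pairs over five corpora), and
Monte-Carlo ensemble checks at 10^4 pairs; the worked-example
reproductions run on the published histograms and tables directly and are
instantaneous. These sizes give sampling tolerances (two percentage points
on rates, one word on length means, half a word on distance means) that
the seeded runs meet with margin.

## Known limitations

* The CL setting is a correctness penalty, not a separate training
  process; systematic cross-corpus transfer effects (e.g. threshold
  mismatch under different class ratios) are not modeled beyond the flat
  penalty.
* With the default latent difficulty link, surface features carry little
  information about the combined difficulty classes — by construction;
  use the surface link to study feature recovery.
* Under the default profiles the universal difficult class is dominated
  by positive pairs (negative-leaning classifiers rarely misclassify the
  same negative across the whole roster). Sign-specific difficulty sets
  can be had compositionally by computing success levels on one gold
  class and cutting that histogram.
* The chi-square overlap p is asymptotic; for tiny universes use the
  printed one-sided p only qualitatively (the tests quantify the error
  against exact enumeration).
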