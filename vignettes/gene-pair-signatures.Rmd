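---
title: "Rank-based gene-pair signatures: model, assumptions and design choices"
author: "reogps"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Rank-based gene-pair signatures: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Quantitative transcriptional predictors of chemotherapy response score a
sample by its expression *values*, which makes them hostage to
normalization: a single clinical sample can only be scored after being
normalized together with a batch of reference samples, and batch,
platform and degradation effects move the values themselves. The
rank-based alternative implemented here — in the tradition of the
top-scoring-pairs (TSP/k-TSP) family — classifies a sample using only
the *relative expression ordering* (REO) of gene pairs within that
sample: whether gene *i* is expressed above gene *j*. Any strictly
increasing per-sample transform leaves every such ordering unchanged, so
a REO classifier needs no cross-sample normalization and applies to one
sample at a time.

The pipeline has four statistical stages, mirroring how such signatures
are discovered for chemotherapy-response cohorts (here: responders =
complete/partial response, non-responders = progressive disease;
stable-disease samples are not dichotomized and are excluded from
training):

1. **Response-gene screen.** For every gene, the Spearman rank
   correlation with a continuous response measure (tumor lesion size) is
   tested; genes with two-sided `p < 0.05` and `|rho| > 0.3` are
   retained. No multiple-testing correction is applied — the screen is a
   deliberate raw-p funnel stage, not an inference.
2. **Pair construction and screening.** All unordered pairs containing
   at least one response gene are candidates
   (`C(m,2) + m(G − m)` of them for `m` marked genes in a `G`-gene
   universe). Each pair is oriented by its *expression difference*

   ED_ij = mean over responders of (E_i − E_j) − mean over
   non-responders of (E_i − E_j),

   so that the stored orientation has ED > 0 (ED = 0 pairs are
   uninformative and dropped). Pairs whose within-sample differences
   E_i − E_j separate the response groups (two-sided Wilcoxon rank-sum,
   `p < 0.01`) are kept, and finally a one-sided exact binomial test
   requires each pair's vote (E_i > E_j calls "responder") to beat the
   no-information rate at level 0.05.
3. **Greedy forward selection.** Candidates are ranked by their
   accuracy-style F-score, `(TP+TN)/(TP+TN+FP+FN)`. Each of the top 20
   seeds a signature that grows by the single pair giving the largest
   strict accuracy increase under majority-vote classification,
   stopping when no addition strictly improves; the best of the 20
   signatures wins (ties: fewer pairs, then deterministic order).
4. **Evaluation.** Confusion metrics (responder = positive class), the
   rank-based (Mann–Whitney) AUC of the integer scores, Kaplan–Meier
   curves, and univariate/multivariate Cox proportional-hazards models
   of progression-free survival on the predicted groups.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `p_threshold`, `r_threshold` | 0.05, 0.3 | response-gene screen cutoffs (raw two-sided p; absolute Spearman rho) |
| `wilcoxon_p_threshold` | 0.01 | pair screen cutoff (raw two-sided p) |
| `binomial_alpha` | 0.05 | level of the one-sided exact binomial filter |
| `binomial_null_p` | majority-class proportion | the no-information rate of the training labels (e.g. 36/47) |
| `n_seeds` | 20 | seeds for forward selection |
| `max_pairs` | 11 | safety bound on signature growth |
| `candidate_cap` | 10,000 | forward-selection pool cap (pairs passing both filters, best first) |
| `vote_threshold` | ceiling(k/2) | responder call at k signature pairs (2 of 3) |

## Design choices where the design was open

**Wilcoxon on differences, not on the binary vote.** The pair screen
compares the within-sample differences E_i − E_j between response
groups. A rank-sum test on the binary ordering indicator degenerates to
a two-proportion test and discards the magnitude structure; the
difference view keeps the screen a genuine rank-sum test while the
downstream classifier still uses only the sign. The consequence —
worth stating plainly — is that the *screen* is not invariant to
per-sample monotone distortion (differences change even when orderings
do not); every quantity from the vote onward (confusion counts,
F-scores, binomial p-values, signature scores, classifications, AUC) is
bit-identical under such distortion, and the test suite asserts exactly
that boundary.

**Exact test branches.** The rank-sum p-value uses the exact null
distribution when the two groups total at most 25 samples with no tied
differences, and the normal approximation with tie and continuity
corrections otherwise (the 36+11 training design uses the latter). The
exact branch is validated against full enumeration of all group
assignments for group sizes up to 5.

**The binomial filter's null.** The "exact binomial test" needs a null
success probability and a sidedness, neither of which is canonical. We
use the one-sided upper tail against the no-information rate — the
accuracy of always predicting the majority class (36/47 ≈ 0.766 in the
emulated training design). Anything below that rate is achievable
without looking at the data, so "significantly better than majority
guessing" is the weakest defensible claim of predictive ability.

**Vote threshold at even sizes.** The published rule is "responder if
at least 2 of 3 pairs vote responder". Its generalization is ambiguous
at even sizes. During forward selection we threshold at
`ceiling(k/2)` ("at least half"), which equals the strict majority at
every odd size. The alternative — strict majority `floor(k/2)+1` at
even sizes too — turns a 2-pair signature into an AND rule, which can
only remove responder calls; starting from a high-specificity seed no
2-pair AND can improve accuracy, so greedy growth with strict
improvement would freeze at a single pair. The "at least half" rule
keeps even sizes a true majority vote and lets selection traverse them.
`default_threshold()` still exposes the strict-majority convention for
standalone use.

**Tie handling.** A sample with E_i = E_j votes non-responder (the
responder-indicating pattern is the strict ordering). All candidate
orderings and tie-breaks are deterministic:
(−F-score, Wilcoxon p, gene_i, gene_j) for candidate ranking; first in
that order among equal-gain additions; fewer pairs, then seed order,
among equal-accuracy seed signatures. Accuracy comparisons during
selection are made on integer correct-counts, never on floating-point
ratios.

**Survival coding.** The Cox models code the predicted group with
non-responder as the reference level, so the reported hazard ratio is
responder vs non-responder and values below 1 mean predicted responders
progress more slowly. Ties in event times use Efron's method;
confidence intervals are Wald on the log-hazard scale.

## What the synthetic generator emulates — and what it does not

`simulate_dataset()` produces the study conditions all tests run under:
a ~2,000-gene × 47-sample cohort (36 responders / 11 non-responders by
default), i.i.d. Gaussian background expression on a log2-like scale
(mean 7, sd 1.5), a lesion-size measure 1.5 sd larger in
non-responders, a block of response genes with latent correlation
|r| = 0.6 to that measure (both signs), planted informative pairs whose
responder-indicating ordering holds with probability 1 − flip in
responders and flip in non-responders (imposed by swapping the two
genes' values within a sample, which preserves marginals and makes the
ordering probabilities exact), exponential progression-free survival
with a non-responder/responder hazard ratio of 2, and independent
exponential censoring calibrated to a 20% marginal rate. Each planted
pair's gene *i* is itself lesion-correlated (negatively: high in the
small-lesion responders), because a pair can only enter the candidate
universe by containing a response gene.

Deliberately *not* emulated: probe-level microarray structure and RMA
preprocessing (the pipeline starts from a collapsed gene × sample
matrix; `collapse_probes()` covers the probe-to-gene rules for real
platforms), gene–gene co-expression networks, non-exponential hazards,
and informative censoring. Passing tests therefore demonstrate that the
statistical machinery recovers planted signal under clean conditions
and is exactly rank-invariant; they do not certify performance on real
cohorts, where correlated genes shrink the effective number of
independent candidate pairs and response labels carry RECIST
measurement error.

One property of these study conditions deserves emphasis: with a flip
probability of 0.05 and 47 training samples, a *single* planted pair
classifies the whole training set perfectly with probability
0.95^47 ≈ 0.09. Since greedy growth stops when accuracy stops strictly
improving, training accuracy typically saturates after one or two
pairs, and the selected signature — while almost always seeded by and
composed mostly of planted pairs — frequently does not need all three.
Recovering the full planted set would require either weaker planted
signal or more training samples than these conditions provide.

## Numerical choices and degenerate inputs

- Spearman p-values use the t approximation on rho with n − 2 degrees
  of freedom (average ranks on ties); an exact option exists for
  n ≤ 10. Zero-variance genes are skipped and counted, never NA'd.
- The analytic power of the correlation screen uses the critical-r
  construction: the critical correlation from the t distribution,
  compared on the Fisher-z scale with sd 1/sqrt(n−3) and the
  small-sample mean correction r/(2(n−1)). At n = 21 and r = 0.3 this
  gives 0.27. It is the power of the correlation test under bivariate
  normality; a Monte-Carlo of the rank test itself at such a small n
  runs a few points lower, and the two converge by n ≈ 200 (asserted in
  the tests at that size).
- `binomial_filter` with null probability 1 can never pass; confusion
  tables summing to zero, empty label groups, missing signature genes,
  and non-finite expression all raise immediate, named errors.
- Survival validation returns a `not estimable` flag (not an error)
  when a predicted group is empty or no events occurred.

## Problem sizes used by the shipped analyses and tests

The analysis scripts and the test suite run the full pipeline at 2,000
genes × 47 samples (~244,000 candidate pairs through the screens), the
selection-recovery experiment at 20 replicates × 503 candidates, the
survival-coverage experiment at 200 replicates of n = 200, and the
Monte-Carlo power checks at 4,000–10,000 replicates. These sizes were
chosen so each property is measured with useful precision while a full
run of everything stays in the minutes range on a single core; the same
code paths scale to the ~20,000-gene, 14.6-million-pair regime of real
cohorts via the block-streaming pair screen.

## Known limitations

- The pair screen's Wilcoxon stage tests differences, so screening
  (unlike classification) can select slightly different pair sets on
  differently distorted versions of the same cohort.
- Greedy forward selection maximizes training accuracy with no internal
  cross-validation, faithfully reproducing the discovery procedure it
  implements; reported training F-scores are optimistic by
  construction, and survival validation on independent predictions is
  the intended guard.
- The exact binomial filter treats per-sample votes as independent
  Bernoulli trials, which ignores the correlation induced by shared
  genes across pairs; it is a screening heuristic, not a calibrated
  test.
- Covariate encodings for the multivariate Cox model are taken as the
  user supplies them; no factor grouping is imposed.
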