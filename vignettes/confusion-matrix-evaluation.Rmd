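---
title: "Evaluating two-class confusion matrices: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating two-class confusion matrices: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmeval)
```

## The objects

A binary classification with hard labels produces a single 2×2 confusion
matrix: TP and FN count the reference positives predicted positive and
negative, FP and TN the reference negatives. `cmeval` stores this as a
small S4 object (`ConfusionMatrix`) with validity checks (non-negative
integer cells, N ≥ 1), alongside a share-based twin
(`RelativeConfusionMatrix`, cells summing to 1) that removes the
sample-size dimension and is convenient for comparing matrices across N.
All metric generics accept either form.

The matrix is equivalently described by the lossless coordinates
`(N, φ, TPR, TNR)` — sample size, prevalence, and the two
class-conditional rates (`RateParameterization`). The forward map is
`TP = N·TPR·φ`, `FN = N·(1−TPR)·φ`, `TN = N·TNR·(1−φ)`,
`FP = N·(1−TNR)·(1−φ)`. Two things about the inverse are worth making
explicit:

* when a reference class is absent (φ ∈ {0, 1}) the rate of that class
  multiplies a zero share and is not identifiable from the matrix; the
  package stores it as `NA` and the round-trip tests skip it. This is an
  information-theoretic necessity, not an implementation shortcut.
* `shares × N` need not be integer. `cmFromRates(..., output="counts")`
  rounds by the largest-remainder method, which preserves N exactly and
  moves every cell by less than one count; if any cell moves by ≥ 0.5
  the requested rates are not representable at that N and a warning is
  raised. Ties in the remainders are broken in the fixed cell order
  (tp, fn, fp, tn) so the result is deterministic.

## Undefined values

Each basic rate has the form `x/(x+y)`. Along different approach paths to
`(0, 0)` that expression converges to different values, so no limit
exists and there is no principled number to substitute when the
denominator vanishes. The package therefore keeps a hard distinction:

* undefined metrics are `NA_real_` — R's idiomatic distinguished
  non-number, which propagates through arithmetic on its own — and are
  serialized as the literal string `"undefined"` in CSV and report
  output, never as 0 or 0.5;
* MCC is the one exception: its 0/0 cases can be consistently closed by
  assigning 0 (the matrix carries no correlation signal), and the
  package uses this total extension so MCC exists for every matrix. The
  perfect-degenerate matrices (`tp = N` or `tn = N`) also receive 0;
  because that value is arguably surprising for a perfect one-class
  prediction, `metricPanel()` attaches an explicit degeneracy note
  rather than letting the 0 pass silently.
* zero tests on denominators are exact for count matrices (integers) and
  use a 1e-12 tolerance for relative matrices (doubles).

F1 follows the propagation rule: it is undefined when PPV or TPR is
undefined or when `PPV + TPR = 0`, even though the algebraically
rearranged form `2TP/(2TP+FP+FN)` would be computable in some of those
cases — silently switching formulas would reintroduce the substitution
problem the `NA` semantics exist to avoid.

## Identities and tolerances

All inter-metric identities (the affine BA–BM link, the product form of
MCC, the φ/β bridges between MCC, BM and MK, the geometric-mean form,
and the two expressions for β) are smooth rational/radical functions of
the counts, so double precision supports a tight absolute tolerance:
`checkAllIdentities()` uses 1e-10 on metrics whose magnitude is at most
1. The test suite verifies the identities exhaustively on every
non-degenerate matrix with N ≤ 30 and on 10,000 random matrices with
N = 40,000; an N this large stresses the floating-point path (marginal
products ≈ 2.6e18) without slowing the suite.

The geometric-mean identity `MCC = ±√(BM·MK)` leaves its sign formally
unresolved; since the bridge prefactors are positive, BM, MK and MCC
always share their sign, and the implementation takes the sign from BM.
Calling `mccGeometricMean()` with inputs of strictly opposite sign is an
error, because no single matrix can produce them.

## Exhaustive enumeration and the correlation curves

For a given N there are `choose(N+3, 3)` confusion matrices (stars and
bars). `enumerateCMs()` materializes them all; at the default curve grid
(N up to 100, ≤ 176,851 rows) this is cheap and keeps the code simple
and vectorized. `pccCurve()` computes the Pearson correlations between
MCC, BM and MK over each enumeration.

The exclusion policy for undefined metrics is a genuine design choice:
the correlation between a pair drops a matrix only when a metric *of
that pair* is undefined (pairwise deletion), and MCC — being total —
never causes exclusion. The number of matrices with undefined BM or MK
is reported per N in the `excluded` column for transparency. A useful
consequence: transposing a matrix (swapping FN and FP) exchanges BM and
MK while leaving MCC unchanged, so under this policy the set of
(MCC, BM) pairs equals the set of (MCC, MK) pairs and
`pcc_mcc_bm == pcc_mcc_mk` exactly, for every N — the package asserts
this at 1e-9.

```{r curve, eval = FALSE}
curve <- pccCurve(5:100)
curve$n[which.min(curve$pcc_mcc_bm)]   # interior minimum, near N ~ 22
```

All three correlations stay above 0.9 on this grid; the curve dips to an
interior minimum near N ≈ 22–25 and then rises. The minimum's exact
location depends mildly on the exclusion policy, which is why the test
asserts a neighbourhood, not a point.

`sampleCMs()` draws matrices uniformly over the *compositions* of N —
the same measure the enumeration uses — via the stars-and-bars bijection
with random 3-subsets of `{1, …, N+3}`. Uniform-over-compositions is not
the distribution of matrices arising from, say, random classifiers on
random data; it is chosen to match the enumeration so that sampled
scatter clouds are a subsample of the exhaustive cloud.

## The known-randomness simulator

`simulateReplicate()` implements an exam-cheating model: n reference
labels are drawn positive with probability φ; a uniformly random subset
of exactly `round(lookup·n)` items is copied from the reference; every
other item is predicted positive with probability `guessBias`,
independently. Conditional on the realized number of positives, the
hypergeometric lookup subset gives

    E[TPR] = lookup + (1−lookup)·guessBias
    E[TNR] = lookup + (1−lookup)·(1−guessBias)

so `E[BM] = lookup` exactly, independent of φ and the guessing bias —
the lookup fraction *is* the classifier's informedness, and
`estimateRandomness()` (= 1 − |BM|) recovers one minus it. MCC and MK do
not have this property: their φ/β prefactors pull them away from the
lookup fraction whenever prevalence and realized bias are dissimilar,
which `randomnessGrid()` makes measurable.

Three generator choices were open and are resolved as follows:

* reference labels are independent Bernoulli(φ) draws, so the realized
  prevalence fluctuates as it would in a freshly collected dataset;
  `fixedCounts = TRUE` gives the exact-count variant instead.
* the copied items form a random subset of exactly `round(lookup·n)`
  items, not per-item Bernoulli(lookup) coins: the subset version keeps
  the copied fraction fixed and the replicate variance lower, matching
  the idea of "a fraction of the answers was copied".
* `guessBias` applies to the random portion only. The alternative
  reading — a target for the *overall* share of positive predictions —
  is available via `biasSemantics = "overall"`, which solves
  `β = lookup·φ + (1−lookup)·q` for the guess probability q and clips it
  to [0, 1]. The default keeps the analytic expectations above exact.
* replicates in which a reference class is absent (possible at small
  n·φ) have undefined BM; they are excluded from the grid summaries and
  counted in `n_excluded`, never averaged in as a substituted number.

The test suite checks BM-recovery at n = 1e5 with 100 replicates per
cell over lookup ∈ {0.25, 0.5, 0.75} and φ, bias ∈ {0.05, 0.5, 0.95},
within three Monte-Carlo standard errors, and checks that MCC breaks
away from the lookup fraction in the φ/β-dissimilar cells. These sizes
keep each replicate's standard error around 3e-3 so the 3-SE band is a
meaningful test, while the whole grid stays fast.

What the simulator does *not* emulate: correlated errors, drifting
prevalence, probabilistic scores and thresholds, or any structure in the
feature space. Passing its tests shows the metrics behave as derived
under the model's independence assumptions — not that any real
classifier is well described by a lookup-plus-guessing process.

## Ranking and reporting

`rankClassifiers()` sorts by one metric, descending, with a stable sort
(ties keep input order and share a tie group; equality is judged at
1e-12 to absorb floating-point noise). Classifiers whose metric is
undefined cannot be ordered by it; they are placed last and flagged
rather than dropped or given a fake value. The bundled comparison
fixtures demonstrate the central caveat: MCC rankings are only
comparable across datasets of equal prevalence, and the same pair of
classifiers can swap winners between the MCC and BM orderings.

Displayed values are rounded to three decimals (the package-wide display
convention); computation always proceeds at full precision, and CSV
output can opt out of rounding with `precision = NA`.

## Known limitations

* Only hard 2×2 matrices: no probabilistic scores, thresholds, ROC/PR
  curves, or multi-class generalizations.
* No uncertainty quantification for metrics from finite N; all reported
  numbers are point values of the observed matrix.
* The enumeration keeps each N's matrices in memory (fine to N of a few
  hundred; the default grid stops at 100).
* Uniformity of `sampleCMs()` is over compositions, which weights
  extreme matrices far more heavily than most data-generating processes
  would.
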