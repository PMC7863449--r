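# cmeval — two-class confusion-matrix evaluation

`cmeval` is an R toolkit for evaluating binary classifications from their
2×2 confusion matrices (TP, FN, FP, TN). It is aimed at anyone who has to
summarize, compare or rank classifiers — machine-learning practitioners,
bioinformaticians benchmarking predictors, epidemiologists reading
diagnostic-test studies — and who needs to understand *why* different
summary metrics can tell different stories about the same matrix.

## The metrics and the relationships between them

For a matrix with sample size N = TP+FN+FP+TN, the basic rates are

    TPR = TP/(TP+FN)   TNR = TN/(TN+FP)   PPV = TP/(TP+FP)   NPV = TN/(TN+FN)

with complements FNR, FPR, FDR, FOR. The multi-category metrics are

    MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))
    BA  = (TPR+TNR)/2          (balanced accuracy)
    BM  = TPR+TNR−1            (bookmaker informedness = Youden's J)
    MK  = PPV+NPV−1            (markedness)

A rate whose denominator is zero is **undefined**: `x/(x+y)` has no limit
at the origin, so no number can stand in for it. `cmeval` represents
undefined metrics as `NA` and serializes them as the literal
`"undefined"`. MCC alone is extended to the whole domain (value 0
whenever a marginal vanishes), so it is defined for every matrix.

Writing φ = (TP+FN)/N for the prevalence and β = (TP+FP)/N for the bias
(the share of positive predictions), the package implements and
numerically verifies the identities that link the metrics:

    BA  = (BM+1)/2
    MCC = √((φ−φ²)/(β−β²)) · BM  =  √((β−β²)/(φ−φ²)) · MK
    MK  = ((φ−φ²)/(β−β²)) · BM
    MCC = sign(BM)·√(BM·MK)
    PPV = TPR·φ / (TPR·φ + (1−TNR)(1−φ))     (and NPV analogously)

These explain when the metrics disagree: BM depends only on the
classifier (TPR, TNR); MCC and MK also absorb the dataset's prevalence.
The package ships the worked-example matrices where the disagreements are
extreme, an exhaustive enumerator of all `choose(N+3, 3)` matrices of a
given N with Pearson-correlation curves between the metrics, and a
simulator of classifiers with *known* randomness (a lookup fraction
copied from the truth, the rest guessed), for which `BM = lookup
fraction` in expectation regardless of prevalence and bias while MCC and
MK drift.

## Worked example

```r
library(cmeval)

cm1 <- loadFixture("CM1")[[1]]   # TP=100 FN=1 FP=5000 TN=94900
round(mcc(cm1), 3)               # 0.136
round(bookmaker(cm1), 2)         # 0.94
round(ppvFromRates(0.99, 0.95, 0.001), 3)   # 0.019
```

The classifier behind `CM1` is well informed (BM = 0.94: TPR 0.99, TNR
0.95), yet its MCC is only 0.136 — at prevalence ≈ 0.001 almost all
positive predictions are false, PPV ≈ 0.02. A positive test still raises
the probability of disease by a factor of ≈ 19 (PPV/φ), which is what
`useCaseReport("CM1")` prints as a pre-/post-test table. Ranking the
bundled two-classifier comparison flips winners depending on the metric:

```r
rankClassifiers(loadFixture("UC4_separate"), "mcc")$name   # "A@1" "B@2"
rankClassifiers(loadFixture("UC4_separate"), "bm")$name    # "B@2" "A@1"
```

Classifier A wins by MCC only because its dataset is balanced; B has the
higher TPR and TNR on both, and BM ranks it first.

## Command line

The installed script `exec/cmeval` wraps the package:

```sh
cmeval metrics --tp 100 --fn 1 --fp 5000 --tn 94900
cmeval batch --in matrices.csv --out panels.csv
cmeval rank --in matrices.csv --metric bm
cmeval usecase --name CM2
cmeval from-rates --n 100001 --prevalence 0.00101 --tpr 0.9901 --tnr 0.94995
cmeval identities --tp 70 --fn 30 --fp 30 --tn 70
cmeval enumerate --n-min 5 --n-max 100 --out curve.csv
cmeval scatter --count 100000 --n 40000 --seed 1 --out scatter.csv
cmeval simulate --n 100000 --prevalence 0.5 --lookup 0.75 --bias 0.5 --reps 100 --seed 1
```

CSV batches use columns `name,tp,fn,fp,tn`; a first line `# relative=true`
marks share-based matrices. Undefined metrics appear as `undefined`.

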