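test_that("constructors validate their invariants", {
  expect_s4_class(ConfusionMatrix(1, 2, 3, 4), "ConfusionMatrix")
  expect_error(ConfusionMatrix(-1, 0, 0, 5), "non-negative")
  expect_error(ConfusionMatrix(0, 0, 0, 0), "N must be >= 1")
  expect_error(ConfusionMatrix(1.5, 0, 0, 5), "integer")
  expect_error(RelativeConfusionMatrix(0.5, 0.5, 0.5, 0.5), "sum to 1")
  expect_s4_class(RelativeConfusionMatrix(0.25, 0.25, 0.25, 0.25),
                  "RelativeConfusionMatrix")
})

test_that("basic rates match their defining ratios and undefined rule", {
  r <- basicRates(ConfusionMatrix(100, 1, 5000, 94900))
  expect_equal(unname(r["tpr"]), 100 / 101)
  expect_equal(unname(r["tnr"]), 94900 / 99900)
  expect_equal(round(unname(r["tpr"]), 2), 0.99)
  expect_equal(round(unname(r["tnr"]), 2), 0.95)

  perf <- basicRates(ConfusionMatrix(50, 0, 0, 50))
  expect_equal(unname(perf[c("tpr", "tnr", "ppv", "npv")]), rep(1, 4))

  z <- basicRates(ConfusionMatrix(0, 0, 3, 7))
  expect_true(isUndefined(z["tpr"]))
  expect_equal(unname(z["tnr"]), 0.7)
  expect_equal(unname(z["ppv"]), 0)
  expect_equal(unname(z["npv"]), 1)
  # complements undefined exactly when the base rate is
  expect_true(isUndefined(z["fnr"]))
  expect_equal(unname(z["fpr"]), 0.3)
})

test_that("MCC matches printed examples and is total", {
  expect_equal(round(mcc(ConfusionMatrix(100, 1, 5000, 94900)), 3), 0.136)
  expect_equal(round(mcc(ConfusionMatrix(90000, 0, 10, 1)), 3), 0.301)
  expect_identical(mcc(ConfusionMatrix(25, 25, 25, 25)), 0)
  # zero-extension: empty marginals (incl. perfect-degenerate) give 0
  expect_identical(mcc(ConfusionMatrix(10, 0, 0, 0)), 0)
  expect_identical(mcc(ConfusionMatrix(0, 0, 0, 10)), 0)
  expect_identical(mcc(ConfusionMatrix(0, 5, 5, 0)), -1)
  expect_true(grepl("perfect-degenerate",
                    paste(panelNotes(metricPanel(ConfusionMatrix(10, 0, 0, 0))),
                          collapse = " ")))
})

test_that("BA/BM/MK examples and undefinedness conditions", {
  cm2 <- ConfusionMatrix(90000, 10000, 1, 9)
  expect_equal(balancedAccuracy(cm2), 0.9)
  expect_equal(bookmaker(cm2), 0.8)
  expect_equal(round(markedness(cm2), 3), 0.001)

  # no reference negatives: TNR undefined, so BA and BM are too
  deg <- ConfusionMatrix(5, 5, 0, 0)
  expect_true(isUndefined(balancedAccuracy(deg)))
  expect_true(isUndefined(bookmaker(deg)))
  expect_equal(markedness(deg), 0)  # PPV=5/5=1, NPV=0/5=0: still defined
  # no negative predictions: NPV undefined, so MK is
  expect_true(isUndefined(markedness(ConfusionMatrix(5, 0, 5, 0))))
})

test_that("accuracy equals its rate-space form; F1 follows the
           zero-denominator rule", {
  expect_equal(accuracy(ConfusionMatrix(50, 0, 0, 50)), 1)
  expect_equal(f1Score(ConfusionMatrix(50, 0, 0, 50)), 1)

  set.seed(11)
  for (i in 1:50) {
    m <- randomCMs(1, 200)
    cm <- ConfusionMatrix(m[1], m[2], m[3], m[4])
    rp <- rateParam(cm)
    tpr <- rp@tpr; tnr <- rp@tnr; phi <- rp@phi
    if (!is.na(tpr) && !is.na(tnr))
      expect_equal(accuracy(cm), tpr * phi + tnr * (1 - phi),
                   tolerance = 1e-12)
  }

  cm0 <- ConfusionMatrix(0, 10, 0, 10)
  expect_equal(accuracy(cm0), 0.5)
  expect_true(isUndefined(f1Score(cm0)))  # PPV is 0/0
})

test_that("metricPanel is consistent with single metrics and idempotent", {
  cm1 <- ConfusionMatrix(100, 1, 5000, 94900)
  p <- metricPanel(cm1)
  expect_equal(round(mcc(p), 3), 0.136)
  expect_equal(round(bookmaker(p), 2), 0.94)
  expect_equal(mcc(p), mcc(cm1))
  expect_equal(basicRates(p), basicRates(cm1))
  expect_equal(metricPanel(cm1)@values, p@values)

  p2 <- metricPanel(ConfusionMatrix(90000, 10000, 1, 9))
  expect_equal(round(mcc(p2), 3), 0.027)

  v <- p@values
  expect_equal(unname(v["fdr"]), 1 - unname(v["ppv"]))
  expect_equal(unname(v["fnr"]), 1 - unname(v["tpr"]))
  expect_equal(unname(v["fpr"]), 1 - unname(v["tnr"]))
  expect_equal(unname(v["for"]), 1 - unname(v["npv"]))
  expect_equal(unname(v["ba"]), (unname(v["bm"]) + 1) / 2)

  pn <- metricPanel(ConfusionMatrix(7, 0, 0, 0))
  expect_equal(unname(pn@values["tpr"]), 1)
  expect_equal(unname(pn@values["ppv"]), 1)
  expect_true(isUndefined(pn@values["tnr"]))
  expect_true(isUndefined(pn@values["npv"]))
})

test_that("label swap is an involution that preserves MCC/BA/BM/MK", {
  cm2 <- ConfusionMatrix(90000, 10000, 1, 9)
  sw <- swapLabels(cm2)
  expect_equal(cmCounts(sw),
               c(tp = 9, fn = 1, fp = 10000, tn = 90000))
  expect_equal(round(mcc(sw), 3), 0.027)

  sym <- ConfusionMatrix(4, 7, 7, 4)
  expect_equal(cmCounts(swapLabels(sym)), cmCounts(sym))

  set.seed(21)
  for (i in 1:40) {
    m <- randomCMs(1, 150)
    cm <- ConfusionMatrix(m[1], m[2], m[3], m[4])
    expect_equal(cmCounts(swapLabels(swapLabels(cm))), cmCounts(cm))
    a <- metricPanel(cm)@values
    b <- metricPanel(swapLabels(cm))@values
    for (k in c("mcc", "ba", "bm", "mk"))
      if (!is.na(a[k]) && !is.na(b[k]))
        expect_equal(unname(a[k]), unname(b[k]), tolerance = 1e-12)
  }
})

test_that("cmFromLabels tabulates correctly and validates input", {
  cm <- cmFromLabels(c(1, 1, 0), c(1, 0, 0))
  expect_equal(cmCounts(cm), c(tp = 1, fn = 1, fp = 0, tn = 1))

  set.seed(5)
  v <- sample(0:1, 60, replace = TRUE)
  same <- cmFromLabels(v, v)
  expect_equal(unname(cmCounts(same)["fn"]), 0)
  expect_equal(unname(cmCounts(same)["fp"]), 0)

  ref <- sample(0:1, 1000, replace = TRUE)
  prd <- sample(0:1, 1000, replace = TRUE)
  expect_equal(cmN(cmFromLabels(ref, prd)), 1000)
  expect_equal(unname(cmCounts(cmFromLabels(ref, prd))["tp"] +
               cmCounts(cmFromLabels(ref, prd))["fn"]), sum(ref))

  expect_error(cmFromLabels(c(1, 0), c(1, 0, 0)), "equal length")
  expect_error(cmFromLabels(c(1, 2, 3), c(1, 1, 1)), "binary")
})

test_that("defined metrics stay inside their ranges", {
  set.seed(31)
  m <- rbind(randomCMs(200, 500), enumOracle(3))
  tab <- metricTable(m)
  for (k in c("tpr", "tnr", "ppv", "npv", "ba", "accuracy", "f1"))
    expect_true(all(tab[[k]] >= 0 & tab[[k]] <= 1, na.rm = TRUE))
  for (k in c("mcc", "bm", "mk"))
    expect_true(all(abs(tab[[k]]) <= 1 + 1e-12, na.rm = TRUE))
  expect_false(anyNA(tab$mcc))  # MCC is total
})

test_that("MCC equals the label-vector Pearson correlation (small oracle)", {
  for (n in c(4, 9, 12)) {
    m <- enumOracle(n)
    for (i in seq_len(nrow(m))) {
      lab <- labelsFromCM(m[i, 1], m[i, 2], m[i, 3], m[i, 4])
      r <- suppressWarnings(stats::cor(lab$ref, lab$pred))
      cm <- ConfusionMatrix(m[i, 1], m[i, 2], m[i, 3], m[i, 4])
      if (!is.na(r)) expect_equal(mcc(cm), r, tolerance = 1e-12)
    }
  }
})
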