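test_that("bundled fixtures hold the printed matrices", {
  expect_equal(cmCounts(loadFixture("CM1")[[1]]),
               c(tp = 100, fn = 1, fp = 5000, tn = 94900))
  expect_equal(cmCounts(loadFixture("CM2")[[1]]),
               c(tp = 90000, fn = 10000, fp = 1, tn = 9))
  expect_equal(cmCounts(loadFixture("CM3")[[1]]),
               c(tp = 90000, fn = 0, fp = 10, tn = 1))
  expect_length(loadFixture("UC4_crossed"), 4)
  expect_error(loadFixture("CM9"), "unknown fixture")
})

test_that("fixture relative forms match their printed shares to 3
           significant figures", {
  printed <- list(
    CM1 = c(9.99e-4, 9.99e-6, 0.05, 0.95),
    CM2 = c(8.99e-1, 9.99e-2, 9.99e-6, 8.99e-5),
    CM3 = c(0.999877792, 0, 1.11e-4, 1.11e-5))
  for (nm in names(printed)) {
    rel <- unname(cmCounts(relativeForm(loadFixture(nm)[[1]])))
    # per-cell agreement to 3 significant figures
    expect_true(all(abs(rel - printed[[nm]]) <=
                    pmax(5e-3 * printed[[nm]], 1e-9)), info = nm)
  }
})

test_that("ranking is stable, descending, and places undefined last", {
  cms <- loadFixture("UC4_separate")
  byMcc <- rankClassifiers(cms, "mcc")
  byBm <- rankClassifiers(cms, "bm")
  expect_equal(byMcc$name[1], "A@1")
  expect_equal(byBm$name[1], "B@2")
  expect_true(all(diff(byMcc$value) <= 0))

  one <- rankClassifiers(list(only = ConfusionMatrix(5, 1, 1, 5)), "mcc")
  expect_equal(one$rank, 1)

  twins <- list(x = ConfusionMatrix(5, 1, 1, 5),
                y = ConfusionMatrix(10, 2, 2, 10))
  tied <- rankClassifiers(twins, "mcc")
  expect_equal(tied$tie_group, c(1, 1))
  expect_equal(tied$name, c("x", "y"))   # input order preserved

  withDeg <- list(good = ConfusionMatrix(8, 2, 2, 8),
                  deg = ConfusionMatrix(5, 5, 0, 0))  # BM undefined
  r <- rankClassifiers(withDeg, "bm")
  expect_equal(r$name, c("good", "deg"))
  expect_true(r$undefined[2])
  expect_error(rankClassifiers(list(), "mcc"), "at least one")
})

test_that("CSV batch IO round-trips counts and serializes undefined", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("name,tp,fn,fp,tn",
               "CM1,100,1,5000,94900",
               "deg,5,5,0,0"), f)
  cms <- readCMBatch(f)
  expect_length(cms, 2)
  expect_false(attr(cms, "relative"))
  expect_equal(cmCounts(cms$CM1), c(tp = 100, fn = 1, fp = 5000, tn = 94900))

  out <- tempfile(fileext = ".csv")
  df <- writeMetricCSV(cms, out)
  expect_equal(round(df$mcc[1], 3), 0.136)
  lines <- readLines(out)
  expect_match(lines[1], "^name,tp,fn,fp,tn,tpr,tnr,ppv,npv,mcc,ba,bm,mk")
  expect_match(lines[3], "undefined")   # degenerate row keeps the literal

  bad <- tempfile(fileext = ".csv")
  writeLines(c("name,tp,fn,fp,tn", "x,-1,0,0,5"), bad)
  expect_error(readCMBatch(bad), "negative")
  writeLines(c("name,tp,fn,fp,tn", "x,1.5,0,0,5"), bad)
  expect_error(readCMBatch(bad), "non-integer")
})

test_that("relative CSV batches are recognized via the comment flag", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("# relative=true",
               "name,tp,fn,fp,tn",
               "relA,0.35,0.15,0.15,0.35"), f)
  cms <- readCMBatch(f)
  expect_true(attr(cms, "relative"))
  expect_s4_class(cms$relA, "RelativeConfusionMatrix")
  expect_equal(mcc(cms$relA), 0.4, tolerance = 1e-12)
})

test_that("the shipped example CSVs load and recompute", {
  f <- system.file("extdata", "use_cases.csv", package = "cmeval")
  cms <- readCMBatch(f)
  expect_equal(round(mcc(cms$CM1), 3), 0.136)
  expect_equal(round(mcc(cms$`B@2`), 1), 0.3)
  fr <- system.file("extdata", "use_cases_relative.csv", package = "cmeval")
  rel <- readCMBatch(fr)
  expect_true(attr(rel, "relative"))
  expect_equal(round(bookmaker(rel$`relA@1`), 1), 0.4)
})

test_that("use-case reports compute their narrative numbers", {
  rep1 <- capture.output(r1 <- useCaseReport("CM1"))
  expect_equal(round(r1$posttest_ratio), 19)
  expect_equal(round(r1$ppv, 2), 0.02)  # exact-rate PPV of the matrix
  expect_lt(r1$one_minus_npv, 1e-4)
  expect_true(any(grepl("factor of 19", rep1)))

  rep2 <- capture.output(r2 <- useCaseReport("CM2"))
  expect_true(any(grepl("misleading", rep2)))
  expect_lt(abs(r2$pessimistic[["mcc"]]), 0.05)
  expect_gt(r2$optimistic[["ba"]], 0.85)

  rep3 <- capture.output(r3 <- useCaseReport("CM3"))
  expect_equal(mcc(loadFixture("CM3")[[1]]), r3$sqrt_bm, tolerance = 0.01)

  rep4 <- capture.output(r4 <- useCaseReport("UC4_separate"))
  expect_equal(r4$ranking_mcc$name[1], "A@1")
  expect_equal(r4$ranking_bm$name[1], "B@2")
  expect_true(any(grepl("flips", rep4)))
})

test_that("the CLI dispatcher drives every subcommand", {
  out <- capture.output(cmevalCLI(c("metrics", "--tp", "100", "--fn", "1",
                                    "--fp", "5000", "--tn", "94900")))
  expect_match(out[2], "0.136")

  f <- system.file("extdata", "use_cases.csv", package = "cmeval")
  out <- capture.output(res <- cmevalCLI(c("rank", "--in", f,
                                           "--metric", "bm")))
  expect_equal(res$name[1], "CM1")   # BM(CM1) = 0.94 tops the batch
  expect_lt(match("B@1", res$name), match("A@1", res$name))

  out <- capture.output(res <- cmevalCLI(
    c("from-rates", "--n", "100001", "--prevalence", "0.00101",
      "--tpr", "0.9901", "--tnr", "0.94995")))
  expect_s4_class(res, "ConfusionMatrix")

  out <- capture.output(res <- cmevalCLI(
    c("identities", "--tp", "70", "--fn", "30", "--fp", "30", "--tn", "70")))
  expect_true(all(res$holds))

  out <- capture.output(res <- cmevalCLI(c("enumerate", "--n-min", "4",
                                           "--n-max", "6")))
  expect_equal(res$count, choose(7:9, 3))

  out <- capture.output(res <- cmevalCLI(
    c("scatter", "--count", "10", "--n", "50", "--seed", "3")))
  expect_equal(nrow(res), 10)

  out <- capture.output(res <- cmevalCLI(
    c("simulate", "--n", "500", "--prevalence", "0.5", "--lookup", "0.5",
      "--bias", "0.5", "--reps", "3", "--seed", "4")))
  expect_equal(res$n_used + res$n_excluded, 3)

  out <- capture.output(res <- cmevalCLI(c("usecase", "--name", "CM3")))
  expect_true("sqrt_bm" %in% names(res))

  expect_output(cmevalCLI(character()), "usage")
  expect_error(cmevalCLI("frobnicate"), "unknown command")
})
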