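pairDT <- function(src, tgt) data.table(source = src, target = tgt)

test_that("the gold standard is the set difference of known pairs", {
  e <- buildSnapshot(makeTriples("a", "r", "b"), typesFor(c("a", "b", "c")), "date2")
  l <- buildSnapshot(makeTriples(c("a", "a"), "r", c("b", "c")),
                     typesFor(c("a", "b", "c")), "date3")
  g <- buildGoldStandard(e, l)
  expect_equal(g, pairDT("a", "c"), ignore_attr = TRUE)
  expect_equal(attr(g, "window"), c("date2", "date3"))
  # later a subset of earlier: empty gold standard
  expect_equal(nrow(buildGoldStandard(l, {
    s <- buildSnapshot(makeTriples("a", "r", "b"), typesFor(c("a", "b")), "date4"); s
  })), 0L)
  expect_error(buildGoldStandard(e, e), "distinct")
})

test_that("training outliers are exactly the date2-confirmed candidates", {
  s1 <- tinySnapshot("date1")                       # A->B->C, so (A, C) hidden
  hk <- abcClosure(s1)
  s2conf <- buildSnapshot(rbind(triples(s1), makeTriples("A", "r9", "C")),
                          semTypes(s1), "date2")
  lab <- labelTrainingOutliers(hk, s2conf)
  expect_equal(lab$outlier, pairDT("A", "C"), ignore_attr = TRUE)
  expect_equal(nrow(lab$normal), 0L)
  expect_equal(lab$outlierFraction, 1)

  lab2 <- labelTrainingOutliers(hk, buildSnapshot(triples(s1), semTypes(s1), "date2"))
  expect_equal(nrow(lab2$outlier), 0L)
  expect_equal(lab2$outlierFraction, 0)
  # partition is exhaustive and disjoint
  expect_equal(nrow(lab2$normal) + nrow(lab2$outlier), length(hk))
})

test_that("confirmation labels recover the generator's planted additions exactly", {
  fx <- suppressMessages(generateFixture(smallSpec()))
  f1 <- suppressMessages(applyFilters(fx$snapshots$date1, fx$filterConfig))
  f2 <- suppressMessages(applyFilters(fx$snapshots$date2, fx$filterConfig))
  hk1 <- abcClosure(f1$snapshot, f1$stoplist)
  lab <- labelTrainingOutliers(hk1, f2$snapshot)
  expect_equal(lab$outlier, fx$groundTruth$additionsDate2[order(source, target)],
               ignore_attr = TRUE)
})

test_that("precision/recall/F1 follow their definitions and algebraic identity", {
  g <- pairDT(c("a", "b"), c("x", "y"))
  r <- evaluateF1(g, g)
  expect_equal(r$f1, 1)
  r2 <- evaluateF1(pairDT("q", "z"), g)
  expect_equal(r2$f1, 0)
  expect_equal(r2$tp, 0L)

  set.seed(12)
  for (i in 1:5) {
    pred <- unique(pairDT(sample(letters, 40, TRUE), sample(letters, 40, TRUE)))
    gold <- unique(pairDT(sample(letters, 30, TRUE), sample(letters, 30, TRUE)))
    r3 <- evaluateF1(pred, gold)
    expect_equal(r3$f1, 2 * r3$tp / (r3$hkSize + r3$gsSize))
    expect_lte(r3$tp, min(r3$hkSize, r3$gsSize))
    expect_equal(r3$tp + r3$fp, r3$hkSize)
    expect_equal(r3$tp + r3$fn, r3$gsSize)
  }
  expect_error(evaluateF1(g, g[0]), "gold")
})

test_that("the large-release F1 arithmetic reproduces the published magnitude", {
  # |predicted| = 5,748,834 and |gold| = 24,772 with 12,413 true positives
  pred <- data.table(source = as.character(seq_len(5748834L)), target = "x")
  gold <- data.table(source = c(as.character(seq_len(12413L)),
                                sprintf("g%d", seq_len(24772L - 12413L))),
                     target = "x")
  r <- evaluateF1(pred, gold)
  expect_equal(r$tp, 12413L)
  expect_equal(round(r$f1, 4), 0.0043)
})

test_that("the paired t-test matches a closed-form oracle and its tail conventions", {
  fA <- c(0.31, 0.22, 0.17, 0.25, 0.4)
  fB <- c(0.35, 0.27, 0.18, 0.24, 0.49)
  d <- fB - fA
  tOracle <- mean(d) / (sd(d) / sqrt(length(d)))
  pOracle <- pt(tOracle, length(d) - 1, lower.tail = FALSE)
  r <- pairedTTest(fA, fB)
  expect_equal(r$tStatistic, tOracle, tolerance = 1e-10)
  expect_equal(r$pValue, pOracle, tolerance = 1e-10)
  expect_equal(r$df, length(d) - 1)
  # one-sided p is half the two-sided p for positive t
  r2 <- pairedTTest(fA, fB, tail = "two.sided")
  expect_equal(r$pValue, r2$pValue / 2, tolerance = 1e-12)
  # symmetric pairing gives t = 0, one-sided p = 0.5
  r0 <- pairedTTest(c(0.1, 0.2), c(0.2, 0.1))
  expect_equal(r0$tStatistic, 0)
  expect_equal(r0$pValue, 0.5)
  expect_error(pairedTTest(c(1, 2), c(2, 3)), "zero-variance")
  expect_error(pairedTTest(1:3 / 10, 1:4 / 10), "equal length")
})

test_that("a full timeslice run is deterministic and robust without planted links", {
  fx <- suppressMessages(generateFixture(smallSpec()))
  run <- function() suppressMessages(runTimesliceExperiment(
    fx$snapshots$date1, fx$snapshots$date2, fx$snapshots$date3,
    config = fx$filterConfig, forestParams = list(seed = 3L), models = "iso"))
  r1 <- run(); r2 <- run()
  expect_identical(lbdrank:::reportJSON(r1), lbdrank:::reportJSON(r2))
  expect_named(r1$evaluations, c("orig", "iso"))
  expect_equal(r1$sizes$gs, r1$evaluations$orig$gsSize)

  # no planted links: the gold standard is background growth only
  fx0 <- suppressMessages(generateFixture(smallSpec(nPlantedInteresting = 0L)))
  r0 <- suppressMessages(runTimesliceExperiment(
    fx0$snapshots$date1, fx0$snapshots$date2, fx0$snapshots$date3,
    config = fx0$filterConfig, forestParams = list(seed = 3L), models = "iso"))
  expect_gt(r0$sizes$gs, 0L)
  expect_equal(r0$evaluations$orig$recall, 1)

  # report serialisation drops rankings and is stable on disk
  f <- withr::local_tempfile(fileext = ".json")
  writeReport(r1, f)
  expect_true(jsonlite::validate(paste(readLines(f), collapse = "\n")))
})

test_that("snapshots must arrive in strictly increasing date order", {
  fx <- suppressMessages(generateFixture(smallSpec()))
  expect_error(runTimesliceExperiment(
    fx$snapshots$date2, fx$snapshots$date1, fx$snapshots$date3,
    config = fx$filterConfig), "increasing")
})
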