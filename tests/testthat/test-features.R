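test_that("PageRank is uniform on a directed cycle and always sums to one", {
  pr <- computePageRank(cycleSnapshot(3))
  expect_equal(unname(pageRankOf(pr)), rep(1 / 3, 3), tolerance = 1e-9)
  for (seed in c(2, 9)) {
    s <- randomSnapshot(40, 0.07, seed = seed)
    w <- pageRankOf(computePageRank(s))
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_true(all(w > 0))
  }
})

test_that("PageRank matches an independent dense power-iteration oracle", {
  for (seed in c(3, 14, 25)) {
    s <- randomSnapshot(30, 0.1, seed = seed)
    mine <- pageRankOf(computePageRank(s, tol = 1e-12))
    oracle <- denseOraclePagerank(s)
    expect_equal(mine, oracle[names(mine)], tolerance = 1e-8)
  }
})

test_that("the damping -> 0 limit approaches the uniform distribution", {
  s <- randomSnapshot(30, 0.1, seed = 6)
  w <- pageRankOf(computePageRank(s, damping = 1e-4))
  expect_equal(unname(w), rep(1 / 30, 30), tolerance = 1e-4)
})

test_that("unconverged iteration warns and records its state", {
  s <- randomSnapshot(30, 0.1, seed = 6)
  expect_warning(pr <- computePageRank(s, tol = 1e-15, maxIter = 3L), "did not converge")
  expect_equal(pr@iterations, 3L)
  expect_false(pr@converged)
})

test_that("feature layouts have the documented width and are input-order invariant", {
  # |S| semantic types and |R| relations give 1 + 3|S| + |R| slots
  ids <- sprintf("C%03d", 1:140)
  tr <- makeTriples(ids[1:139], sprintf("R%02d", rep_len(1:35, 139)), ids[2:140])
  st <- stats::setNames(lapply(1:140, function(i) sprintf("S%03d", ((i * 5) %% 133) + 1)), ids)
  s <- buildSnapshot(tr, st, "date1")
  lay <- buildLayout(s)
  expect_equal(length(lay@semTypes), 133L)
  expect_equal(totalLength(lay), 1L + 3L * 133L + 35L)

  s2 <- tinySnapshot()   # |S| = 3, |R| = 2 -> 12; with |S|=2,|R|=1 -> 8
  lay2 <- buildLayout(buildSnapshot(makeTriples("A", "r", "B"),
                                    list(A = "t1", B = "t2"), "d"))
  expect_equal(totalLength(lay2), 8L)

  # permutation of input rows leaves the layout unchanged
  tr2 <- triples(s)[sample(.N)]
  lay3 <- buildLayout(buildSnapshot(tr2, st, "date1"))
  expect_identical(lay3@semTypes, lay@semTypes)
  expect_identical(lay3@relations, lay@relations)
  expect_equal(featureNames(lay)[1], "number of linking terms")
})

test_that("single-linking-term pairs put one value per block in the right slots", {
  tr <- makeTriples(c("A", "B"), c("r1", "r2"), c("B", "C"))
  st <- list(A = "Disease", B = "Physiologic", C = "Pharmacologic")
  s <- buildSnapshot(tr, st, "date1")
  hk <- abcClosure(s)
  lay <- buildLayout(s)
  pr <- computePageRank(s)
  v <- featurizePair(hk, 1L, lay, pr, semTypes(s))
  expect_equal(unname(v["number of linking terms"]), 1)
  expect_equal(unname(v["A:Disease"]), unname(pageRankOf(pr, "A")))
  expect_equal(unname(v["C:Pharmacologic"]), unname(pageRankOf(pr, "C")))
  expect_equal(unname(v["LT:Physiologic"]), unname(pageRankOf(pr, "B")))
  # exactly one non-zero in each semantic-type block
  expect_equal(sum(v[startsWith(names(v), "A:")] > 0), 1L)
  expect_equal(sum(v[startsWith(names(v), "C:")] > 0), 1L)
  expect_equal(sum(v[startsWith(names(v), "LT:")] > 0), 1L)
  # both legs of (B, r1, r2) hit their relation slots with B's PageRank
  expect_equal(unname(v["relation:r1"]), unname(pageRankOf(pr, "B")))
  expect_equal(unname(v["relation:r2"]), unname(pageRankOf(pr, "B")))
})

test_that("a witness using the same relation on both legs doubles that slot", {
  tr <- makeTriples(c("A", "B"), c("r", "r"), c("B", "C"))
  s <- buildSnapshot(tr, typesFor(c("A", "B", "C")), "date1")
  v <- featurizePair(abcClosure(s), 1L, buildLayout(s), pr <- computePageRank(s), semTypes(s))
  expect_equal(unname(v["relation:r"]), 2 * unname(pageRankOf(pr, "B")))
})

test_that("feature conservation laws hold over a random batch", {
  fx <- suppressMessages(generateFixture(smallSpec()))
  f <- suppressMessages(applyFilters(fx$snapshots$date1, fx$filterConfig))
  hk <- abcClosure(f$snapshot, f$stoplist)
  lay <- buildLayout(f$snapshot)
  pr <- computePageRank(f$snapshot)
  st <- semTypes(f$snapshot)
  X <- featurizeBatch(hk, lay, pr, st)
  p <- candidatePairs(hk)
  lw <- linkWitnesses(hk)
  S <- length(lay@semTypes)
  aBlock <- 1 + seq_len(S); cBlock <- 1 + S + seq_len(S); ltBlock <- 1 + 2 * S + seq_len(S)
  relBlock <- (2 + 3 * S):totalLength(lay)
  w <- pageRankOf(pr)

  expect_equal(as.numeric(X[, 1]), as.numeric(p$nLinkingTerms))
  expect_equal(Matrix::rowSums(X[, aBlock]),
               unname(w[p$source] * lengths(st[p$source])), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(Matrix::rowSums(X[, cBlock]),
               unname(w[p$target] * lengths(st[p$target])), tolerance = 1e-12,
               ignore_attr = TRUE)
  ltSum <- unique(lw[, .(source, target, b)])[, .(s = sum(w[b] * lengths(st[b]))),
                                              by = .(source, target)]
  expect_equal(Matrix::rowSums(X[, ltBlock]), ltSum[p, on = c("source", "target")]$s,
               tolerance = 1e-12, ignore_attr = TRUE)
  relSum <- lw[, .(s = 2 * sum(w[b])), by = .(source, target)]
  expect_equal(Matrix::rowSums(X[, relBlock]), relSum[p, on = c("source", "target")]$s,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("featurization is batch-consistent and permutation-invariant in the links", {
  s <- randomSnapshot(30, 0.12, seed = 41)
  hk <- abcClosure(s)
  lay <- buildLayout(s); pr <- computePageRank(s); st <- semTypes(s)
  X <- featurizeBatch(hk, lay, pr, st)
  for (i in c(1L, min(5L, length(hk)))) {
    expect_equal(unname(featurizePair(hk, i, lay, pr, st)), as.numeric(X[i, ]))
  }
  # shuffling witness rows changes nothing
  hk2 <- hk
  hk2@links <- hk2@links[sample(.N)]
  expect_equal(as.matrix(featurizeBatch(hk2, lay, pr, st)), as.matrix(X))

  empty <- hk[integer(0)]
  X0 <- featurizeBatch(empty, lay, pr, st)
  expect_equal(dim(X0), c(0L, totalLength(lay)))
})

test_that("layout mismatches are fatal rather than silent", {
  s <- tinySnapshot()
  hk <- abcClosure(s)
  pr <- computePageRank(s)
  badLay <- new("FeatureLayout", semTypes = c("t1", "t2"), relations = c("r1", "r2"))
  expect_error(featurizeBatch(hk, badLay, pr, semTypes(s)), "layout mismatch")
})

test_that("sparse triplet export writes a readable matrix and sidecar", {
  s <- randomSnapshot(25, 0.12, seed = 43)
  hk <- abcClosure(s)
  lay <- buildLayout(s)
  X <- featurizeBatch(hk, lay, computePageRank(s), semTypes(s))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeFeatureMatrix(X, lay, f)
  trip <- fread(f)
  M <- Matrix::sparseMatrix(i = trip$row, j = trip$col, x = trip$value, dims = dim(X))
  expect_equal(as.matrix(M), unname(as.matrix(X)))
  side <- fread(paste0(f, ".layout.tsv"))
  expect_equal(side$meaning, featureNames(lay))
})
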