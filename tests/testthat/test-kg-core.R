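test_that("pipe-delimited relation reading aggregates duplicates and tolerates malformed lines", {
  f <- withr::local_tempfile()
  writeLines(rep("C1|may_treat|C2", 3), f)
  tr <- readRRFRelations(f)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$count, 3L)
  expect_false(tr$negative)

  writeLines(character(), f)
  expect_equal(nrow(readRRFRelations(f)), 0L)

  # 1000 lines, 10 malformed: generator bookkeeping gives the expected tally
  good <- sprintf("C%04d|rel|D%04d", 1:990, 1:990)
  bad <- rep("broken_line_without_pipes", 10)
  writeLines(sample(c(good, bad)), f)
  expect_message(tr <- readRRFRelations(f), "10 malformed")
  expect_equal(nrow(tr), 990L)
  expect_equal(sum(tr$count), 990L)

  # mostly-malformed input signals the wrong dialect
  writeLines(c(good[1:5], rep("junk", 20)), f)
  expect_error(suppressMessages(readRRFRelations(f)), "malformed")
  expect_error(readRRFRelations(file.path(tempdir(), "no-such-file.rrf")), "not found")
})

test_that("count columns are honoured and negatives flagged by prefix", {
  f <- withr::local_tempfile()
  writeLines(c("C1|treats|C2|7", "C1|treats|C2|5", "C3|NEG_treats|C4|2"), f)
  tr <- readRRFRelations(f)
  expect_equal(tr[subject == "C1"]$count, 12L)
  expect_true(tr[subject == "C3"]$negative)
})

test_that("predication tables parse with negatives flagged and histograms recovered", {
  f <- withr::local_tempfile()
  writeLines(c("subject_cui\tpredicate\tobject_cui",
               "C1\tTREATS\tC2",
               "C1\tNEG_TREATS\tC2"), f)
  tr <- readPredications(f)
  expect_equal(nrow(tr), 2L)
  expect_equal(tr[predicate == "TREATS"]$negative, FALSE)
  expect_equal(tr[predicate == "NEG_TREATS"]$negative, TRUE)

  # known predicate histogram round-trips
  set.seed(3)
  preds <- sample(c("TREATS", "CAUSES", "AFFECTS"), 300, TRUE, prob = c(.5, .3, .2))
  rows <- sprintf("C%03d,%s,D%03d", seq_along(preds), preds, seq_along(preds))
  writeLines(c("subject_cui,predicate,object_cui", rows), f)
  tr <- readPredications(f)
  expect_equal(
    as.list(tr[, sum(count), by = predicate][order(predicate)]$V1),
    as.list(as.integer(table(preds)))
  )
})

test_that("semantic-type reading accumulates multiple types per concept", {
  f <- withr::local_tempfile()
  writeLines(c("C1|dsyn", "C1|phsu", "C2|fndg"), f)
  st <- readSemTypes(f)
  expect_setequal(st$C1, c("dsyn", "phsu"))
  expect_equal(st$C2, "fndg")

  writeLines(character(), f)
  expect_length(readSemTypes(f), 0L)

  # planted inventory size is recovered exactly
  set.seed(9)
  ids <- sprintf("C%03d", 1:200)
  types <- sprintf("T%02d", 1:12)
  rows <- unlist(lapply(ids, function(i)
    sprintf("%s|%s", i, sample(types, sample(1:3, 1)))))
  writeLines(rows, f)
  st <- readSemTypes(f)
  expect_length(st, 200L)
  expect_setequal(unique(unlist(st)), intersect(types, unique(unlist(st))))
  expect_true(all(lengths(st) >= 1L & lengths(st) <= 3L))
})

test_that("ISA merging collapses classes onto lexicographic representatives", {
  tr <- makeTriples(c("X", "D"), c("ISA", "treats"), c("Y", "X"))
  m <- mergeIsaClasses(tr, "ISA")
  expect_equal(nrow(m$triples), 1L)
  expect_equal(m$triples$subject, "D")
  expect_equal(m$triples$object, "X")      # rep(X, Y) = X
  expect_equal(unname(m$mapping[c("X", "Y")]), c("X", "X"))

  # no ISA triples: identity with an empty mapping
  tr2 <- makeTriples("A", "r", "B")
  m2 <- mergeIsaClasses(tr2, "ISA")
  expect_equal(m2$triples, tr2, ignore_attr = TRUE)
  expect_length(m2$mapping, 0L)
})

test_that("ISA classes match a union-find oracle and merging is idempotent", {
  set.seed(21)
  ids <- sprintf("C%03d", 1:100)
  isa <- data.table(subject = sample(ids, 60, TRUE), object = sample(ids, 60, TRUE))
  isa <- isa[subject != object]
  other <- makeTriples(sample(ids, 150, TRUE), "rel", sample(ids, 150, TRUE))
  other <- other[subject != object]
  tr <- rbind(makeTriples(isa$subject, "ISA", isa$object), other)

  m <- mergeIsaClasses(tr, "ISA")
  oracle <- unionFindClasses(isa)
  expect_equal(m$mapping[sort(names(oracle))], oracle[sort(names(oracle))])

  # idempotence and structural postconditions
  m2 <- mergeIsaClasses(m$triples, "ISA")
  expect_equal(m2$triples, m$triples, ignore_attr = TRUE)
  expect_false(any(m$triples$predicate == "ISA"))
  expect_false(any(m$triples$subject == m$triples$object))

  # merged classes keep the union of member semantic types
  st <- list(X = c("a"), Y = c("b"), Z = c("c"))
  merged <- mergeSemTypes(st, c(X = "X", Y = "X"))
  expect_setequal(merged$X, c("a", "b"))
  expect_equal(merged$Z, "c")
})

test_that("snapshot construction validates endpoints and drops untyped concepts", {
  tr <- makeTriples(c("A", "B", "C"), "r", c("B", "C", "D"))
  st <- list(A = "t1", B = "t2", C = "t1", D = "t3")
  s <- buildSnapshot(tr, st, "date1")
  expect_s4_class(s, "KnowledgeSnapshot")
  expect_equal(length(s), 3L)
  expect_length(conceptIds(s), 4L)
  expect_equal(relationInventory(s), "r")

  # an untyped endpoint drops its triple, with a logged count
  st$D <- character()
  expect_message(s2 <- buildSnapshot(tr, st, "date1"), "dropped 1 triple")
  expect_equal(length(s2), 2L)
  expect_false("D" %in% conceptIds(s2))

  expect_error(buildSnapshot(tr[0], st, "date1"), "empty")
})

test_that("adjacency queries agree with the triple set", {
  s <- tinySnapshot()
  od <- outDegree(s)
  expect_equal(unname(od[c("A", "B", "C")]), c(1L, 1L, 0L))
  kp <- knownPairs(s)
  expect_equal(kp, data.table(source = c("A", "B"), target = c("B", "C")),
               ignore_attr = TRUE)
})

test_that("snapshots round-trip through the pipe-delimited dialect bit-exactly", {
  fx <- suppressMessages(generateFixture(smallSpec()))
  s <- fx$snapshots$date1
  f <- withr::local_tempfile()
  writeRRFRelations(s, f)
  back <- buildSnapshot(readRRFRelations(f), semTypes(s), dateLabel(s))
  expect_equal(triples(back), triples(s), ignore_attr = TRUE)
  expect_identical(readLines(f), { writeRRFRelations(back, f2 <- withr::local_tempfile()); readLines(f2) })
})
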