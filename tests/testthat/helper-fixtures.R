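library(data.table)

# build a triples table from vectors
makeTriples <- function(subject, predicate, object, count = 10L) {
  data.table(
    subject = subject, predicate = predicate, object = object,
    count = as.integer(rep_len(count, length(subject))),
    negative = startsWith(predicate, "NEG")
  )
}

# semantic types: one common type per concept unless overridden
typesFor <- function(ids, type = "t1") {
  stats::setNames(lapply(ids, function(i) type), ids)
}

tinySnapshot <- function(dateLab = "date1") {
  tr <- makeTriples(c("A", "B"), c("r1", "r2"), c("B", "C"))
  buildSnapshot(tr, list(A = "t1", B = "t2", C = "t3"), dateLab)
}

# random directed graph snapshot (no self-loops), uniform single type
randomSnapshot <- function(n, p, seed, dateLab = "date1", nRel = 3L) {
  set.seed(seed)
  ids <- sprintf("N%03d", seq_len(n))
  g <- CJ(subject = ids, object = ids)[subject != object]
  g <- g[runif(nrow(g)) < p]
  if (nrow(g) == 0L) g <- data.table(subject = ids[1], object = ids[2])
  tr <- makeTriples(g$subject, sprintf("r%d", sample.int(nRel, nrow(g), TRUE)), g$object)
  st <- stats::setNames(lapply(ids, function(i) sprintf("t%d", 1L + (match(i, ids) %% 4L))), ids)
  buildSnapshot(tr, st, dateLab)
}

cycleSnapshot <- function(n) {
  ids <- sprintf("V%02d", seq_len(n))
  tr <- makeTriples(ids, "r", ids[c(2:n, 1)])
  buildSnapshot(tr, typesFor(ids), "date1")
}

# independent boolean matrix-product oracle for the A-B-C closure
closureOracle <- function(snapshot, stoplist = character()) {
  ids <- conceptIds(snapshot)
  n <- length(ids)
  M <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  tr <- unique(triples(snapshot)[, .(subject, object)])
  M[cbind(tr$subject, tr$object)] <- TRUE
  keepB <- !(ids %in% stoplist)   # stoplisted concepts cannot act as B
  reach2 <- ((M[, keepB, drop = FALSE] + 0) %*% (M[keepB, , drop = FALSE] + 0)) > 0
  hidden <- reach2 & !M
  diag(hidden) <- FALSE
  w <- which(hidden, arr.ind = TRUE)
  out <- data.table(source = ids[w[, 1]], target = ids[w[, 2]])
  setkey(out, source, target)
  out[]
}

# independent dense power-iteration PageRank oracle
denseOraclePagerank <- function(snapshot, damping = 0.85, tol = 1e-12, maxIter = 1000L) {
  ids <- conceptIds(snapshot)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  tr <- unique(triples(snapshot)[, .(subject, object)])
  A[cbind(tr$subject, tr$object)] <- 1
  od <- rowSums(A)
  x <- rep(1 / n, n)
  for (i in seq_len(maxIter)) {
    contrib <- ifelse(od > 0, x / od, 0)
    xn <- damping * as.numeric(t(A) %*% contrib) +
      damping * sum(x[od == 0]) / n + (1 - damping) / n
    if (sum(abs(xn - x)) < tol) { x <- xn; break }
    x <- xn
  }
  stats::setNames(x / sum(x), ids)
}

# union-find oracle for ISA class formation
unionFindClasses <- function(edges) {
  parent <- new.env()
  find <- function(x) {
    p <- get0(x, envir = parent, ifnotfound = x)
    if (identical(p, x)) return(x)
    r <- find(p); assign(x, r, envir = parent); r
  }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (!identical(ra, rb)) assign(max(ra, rb), min(ra, rb), envir = parent)
  }
  for (i in seq_len(nrow(edges))) union2(edges$subject[i], edges$object[i])
  members <- unique(c(edges$subject, edges$object))
  stats::setNames(vapply(members, find, ""), members)
}

# cache the default synthetic fixture across test files (one generation per run)
fixtureCache <- new.env()
defaultFixture <- function() {
  if (is.null(fixtureCache$fx))
    fixtureCache$fx <- suppressMessages(generateFixture())
  fixtureCache$fx
}

# a small, fast fixture spec for structural tests
smallSpec <- function(...) {
  args <- utils::modifyList(
    list(nConcepts = 800L, clusterSize = 18L, nPeriphery = 30L,
         nPlantedInteresting = 10L, hubCount = 2L, hubOutdegree = 80L,
         growthRate = 0.01, seed = 11L),
    list(...))
  do.call(syntheticSpec, args)
}
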