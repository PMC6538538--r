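#' Build the feature layout for a snapshot
#'
#' The feature array for one hidden-knowledge pair is
#' \code{[n | A-semtype block | C-semtype block | LT-semtype block | relation block]}:
#' slot 1 holds the number of linking terms, then three blocks of one slot
#' per semantic type (for the source term A, the target term C, and the
#' linking terms), then one slot per relation label.  Total width is
#' \code{1 + 3 * |semtypes| + |relations|}.  Both inventories are ordered
#' lexicographically so the layout is reproducible across input permutations.
#'
#' @param snapshot a non-empty \code{KnowledgeSnapshot} (or several, via
#'   [combineLayouts()], when train and test snapshots must share a layout).
#' @return a [FeatureLayout-class].
#' @export
buildLayout <- function(snapshot) {
  st <- sort(unique(unlist(semTypes(snapshot), use.names = FALSE)))
  rel <- sort(relationInventory(snapshot))
  if (length(st) == 0L || length(rel) == 0L)
    stop("cannot build a feature layout from empty inventories")
  new("FeatureLayout", semTypes = st, relations = rel)
}

#' Combine feature layouts over several snapshots
#'
#' Union of the semantic-type and relation inventories, re-sorted; used when
#' a model trained on one snapshot must score candidates from another.
#'
#' @param ... \code{FeatureLayout} objects.
#' @return a \code{FeatureLayout}.
#' @export
combineLayouts <- function(...) {
  ls <- list(...)
  new("FeatureLayout",
    semTypes = sort(unique(unlist(lapply(ls, function(l) l@semTypes)))),
    relations = sort(unique(unlist(lapply(ls, function(l) l@relations)))))
}

#' @rdname FeatureLayout-class
#' @export
setMethod("totalLength", "FeatureLayout",
  function(x) 1L + 3L * length(x@semTypes) + length(x@relations))

#' @rdname FeatureLayout-class
#' @export
setMethod("featureNames", "FeatureLayout", function(x) {
  c("number of linking terms",
    paste0("A:", x@semTypes), paste0("C:", x@semTypes),
    paste0("LT:", x@semTypes), paste0("relation:", x@relations))
})

setMethod("show", "FeatureLayout", function(object) {
  cat(sprintf(
    "FeatureLayout: %d semantic types x 3 blocks + %d relations (+n) = %d slots\n",
    length(object@semTypes), length(object@relations), totalLength(object)
  ))
})

#' Feature vectors for a batch of candidate pairs
#'
#' For each candidate pair (A, C) with linking terms B_1..B_n:
#' \itemize{
#'   \item slot 1: n, the number of distinct linking terms (hypothesised to
#'     be inversely correlated with interestingness);
#'   \item A block: A's PageRank written into \emph{every} semantic-type slot
#'     of A (multi-typed concepts repeat their full weight, no splitting);
#'   \item C block: likewise for C;
#'   \item LT block: for each \emph{distinct} B_i, B_i's PageRank added into
#'     each of B_i's type slots;
#'   \item relation block: for each link witness (B, rel_AB, rel_BC), B's
#'     PageRank added to the slot of rel_AB and to the slot of rel_BC — a B
#'     contributing via two relation pairs counts once in the LT block but
#'     once per witness here.
#' }
#' Rows follow the input pair order; the result is a sparse matrix, so
#' memory stays proportional to the non-zeros.
#'
#' @param candidates a \code{CandidateSet} (or a subset of one).
#' @param layout a [FeatureLayout-class]; any semantic type or predicate of
#'   the batch missing from it is a fatal layout mismatch.
#' @param pagerank a [PageRankWeights-class] covering all involved concepts.
#' @param semtypes named list of per-concept semantic types.
#' @return sparse \code{dgCMatrix}, one row per pair, with
#'   \code{rownames = "source|target"} and \code{colnames = featureNames(layout)}.
#' @export
featurizeBatch <- function(candidates, layout, pagerank, semtypes) {
  p <- candidatePairs(candidates)
  S <- length(layout@semTypes)
  width <- totalLength(layout)
  if (nrow(p) == 0L) {
    m <- sparseMatrix(i = integer(), j = integer(), x = numeric(), dims = c(0L, width))
    colnames(m) <- featureNames(layout)
    return(m)
  }
  l <- linkWitnesses(candidates)
  pr <- pageRankOf(pagerank)

  p <- copy(p)[, row := .I]
  stLong <- data.table(
    id = rep(names(semtypes), lengths(semtypes)),
    type = unlist(semtypes, use.names = FALSE)
  )
  stLong[, slot := match(type, layout@semTypes)]
  relIdx <- function(r) match(r, layout@relations)

  needIds <- unique(c(p$source, p$target, l$b))
  if (!all(needIds %in% names(semtypes)))
    stop("layout mismatch: concepts without semantic types in batch")
  if (!all(needIds %in% names(pr)))
    stop("concepts missing from the PageRank weights")

  aB <- merge(p[, .(row, id = source)], stLong, by = "id", allow.cartesian = TRUE)
  cB <- merge(p[, .(row, id = target)], stLong, by = "id", allow.cartesian = TRUE)
  if (anyNA(aB$slot) || anyNA(cB$slot))
    stop("layout mismatch: unknown semantic type in batch")

  lRow <- merge(l, p[, .(source, target, row)], by = c("source", "target"))
  ltDistinct <- unique(lRow[, .(row, id = b)])
  ltB <- merge(ltDistinct, stLong, by = "id", allow.cartesian = TRUE)
  if (anyNA(ltB$slot)) stop("layout mismatch: unknown semantic type in batch")

  rAB <- lRow[, .(row, id = b, rslot = relIdx(relAB))]
  rBC <- lRow[, .(row, id = b, rslot = relIdx(relBC))]
  if (anyNA(rAB$rslot) || anyNA(rBC$rslot))
    stop("layout mismatch: unknown predicate in batch")
  relEntries <- rbind(rAB, rBC)

  i <- c(p$row, aB$row, cB$row, ltB$row, relEntries$row)
  j <- c(rep(1L, nrow(p)),
         1L + aB$slot,
         1L + S + cB$slot,
         1L + 2L * S + ltB$slot,
         1L + 3L * S + relEntries$rslot)
  x <- c(as.numeric(p$nLinkingTerms),
         pr[aB$id], pr[cB$id], pr[ltB$id], pr[relEntries$id])
  m <- sparseMatrix(i = i, j = j, x = x, dims = c(nrow(p), width))
  rownames(m) <- paste(p$source, p$target, sep = "|")
  colnames(m) <- featureNames(layout)
  m
}

#' Feature vector for a single candidate pair
#'
#' @param candidates a \code{CandidateSet}.
#' @param i index of the pair to featurize.
#' @inheritParams featurizeBatch
#' @return named numeric vector of length \code{totalLength(layout)}.
#' @export
featurizePair <- function(candidates, i, layout, pagerank, semtypes) {
  m <- featurizeBatch(subsetCandidates(candidates, i), layout, pagerank, semtypes)
  stats::setNames(as.numeric(m[1L, ]), colnames(m))
}

#' Write a feature matrix in sparse triplet text form
#'
#' Emits \code{row\\tcol\\tvalue} lines (1-based, ordered by row then column)
#' plus a layout sidecar \code{<path>.layout.tsv} listing slot meanings.
#'
#' @param m sparse feature matrix from [featurizeBatch()].
#' @param layout the layout used to build \code{m}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFeatureMatrix <- function(m, layout, path) {
  tm <- as(as(m, "generalMatrix"), "TsparseMatrix")
  o <- order(tm@i, tm@j)
  dt <- data.table(row = tm@i[o] + 1L, col = tm@j[o] + 1L, value = tm@x[o])
  fwrite(dt, path, sep = "\t")
  side <- data.table(slot = seq_len(totalLength(layout)), meaning = featureNames(layout))
  fwrite(side, paste0(path, ".layout.tsv"), sep = "\t")
  invisible(path)
}
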