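#' A-B-C open-discovery closure
#'
#' Proposes hidden knowledge by the classic two-step closure: every ordered
#' pair (A, C), A != C, connected by at least one directed path A -> B -> C
#' whose linking term B is not stoplisted, and with no direct A -> C triple
#' in the snapshot.  Relation labels on both legs are retained as witnesses
#' for the feature stage, but the closure itself ignores them — the relation
#' is disregarded at the discovery stage.
#'
#' Stoplisted concepts are excluded from the B role only; they may still act
#' as A or C.  Candidate enumeration is deterministic (lexicographic by
#' (A, C)), so output files and downstream sampling are reproducible.
#'
#' @param snapshot a filtered, non-empty \code{KnowledgeSnapshot}.
#' @param stoplist concept ids excluded as linking terms.
#' @return a [CandidateSet-class].
#' @examples
#' tr <- data.table::data.table(
#'   subject = c("A", "B"), predicate = "rel", object = c("B", "C"),
#'   count = 10L, negative = FALSE
#' )
#' st <- list(A = "t1", B = "t2", C = "t1")
#' abcClosure(buildSnapshot(tr, st, "d1"))
#' @export
abcClosure <- function(snapshot, stoplist = character()) {
  if (length(snapshot) == 0L) stop("cannot run the closure on an empty snapshot")
  tr <- unique(triples(snapshot)[, .(subject, predicate, object)])
  ab <- tr[!(object %in% stoplist),
           .(source = subject, b = object, relAB = predicate)]
  bc <- tr[!(subject %in% stoplist),
           .(b = subject, target = object, relBC = predicate)]
  links <- merge(ab, bc, by = "b", allow.cartesian = TRUE)
  links <- links[source != target]
  known <- knownPairs(snapshot)
  links <- links[!known, on = c("source", "target")]
  setcolorder(links, c("source", "target", "b", "relAB", "relBC"))
  setkey(links, source, target, b, relAB, relBC)
  pairs <- links[, .(nLinkingTerms = uniqueN(b)), by = .(source, target)]
  setkey(pairs, source, target)
  new("CandidateSet",
    pairs = pairs[], links = links[], dateLabel = dateLabel(snapshot))
}

#' @rdname CandidateSet-class
#' @export
setMethod("candidatePairs", "CandidateSet", function(x) copy(x@pairs))

#' @rdname CandidateSet-class
#' @export
setMethod("linkWitnesses", "CandidateSet", function(x) copy(x@links))

#' @rdname CandidateSet-class
#' @export
setMethod("dateLabel", "CandidateSet", function(x) x@dateLabel)

#' Number of candidate pairs
#' @param x a \code{CandidateSet}
#' @export
setMethod("length", "CandidateSet", function(x) nrow(x@pairs))

setMethod("show", "CandidateSet", function(object) {
  cat(sprintf(
    "CandidateSet from '%s': %d hidden pairs, %d link witnesses\n",
    object@dateLabel, nrow(object@pairs), nrow(object@links)
  ))
})

# internal: subset a CandidateSet to pair rows `idx` (integer indices)
subsetCandidates <- function(candidates, idx) {
  p <- candidates@pairs[idx]
  l <- candidates@links[p[, .(source, target)], on = c("source", "target")]
  new("CandidateSet", pairs = p, links = l, dateLabel = candidates@dateLabel)
}

#' @rdname CandidateSet-class
#' @param i integer or logical index over candidate pairs
#' @param j,drop,... ignored
#' @export
setMethod("[", "CandidateSet", function(x, i, j, ..., drop = FALSE) {
  if (is.logical(i)) i <- which(i)
  subsetCandidates(x, i)
})

#' Write candidate pairs as TSV
#'
#' Columns: source id, target id, number of linking terms, and the
#' semicolon-joined witnesses \code{B:rel_AB:rel_BC}.
#'
#' @param candidates a \code{CandidateSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCandidates <- function(candidates, path) {
  p <- candidatePairs(candidates)
  l <- linkWitnesses(candidates)
  w <- l[, .(witnesses = paste(sprintf("%s:%s:%s", b, relAB, relBC), collapse = ";")),
         by = .(source, target)]
  out <- w[p, on = c("source", "target")]
  out <- out[order(source, target),
             .(source_id = source, target_id = target,
               n_linking_terms = nLinkingTerms, witnesses)]
  fwrite(out, path, sep = "\t")
  invisible(path)
}
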