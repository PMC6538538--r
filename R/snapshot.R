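#' Build a dated knowledge snapshot
#'
#' Assembles parsed triples and a semantic-type assignment into a validated
#' [KnowledgeSnapshot-class].  Triples with an endpoint lacking any semantic
#' type cannot occupy a feature slot and are dropped with a logged count; the
#' concept inventory is restricted to the surviving triple endpoints, and the
#' relation inventory is the sorted set of surviving predicates.
#'
#' @param triples triples \code{data.table} (see [readRRFRelations()]).
#' @param semtypes named list, concept id -> character vector of types.
#' @param dateLabel ordinal snapshot tag (e.g. \code{"date1"}).
#' @return a \code{KnowledgeSnapshot}.
#' @examples
#' tr <- data.table::data.table(
#'   subject = c("C1", "C2"), predicate = "treats", object = c("C2", "C3"),
#'   count = 10L, negative = FALSE
#' )
#' st <- list(C1 = "dsyn", C2 = "phsu", C3 = "fndg")
#' buildSnapshot(tr, st, "date1")
#' @export
buildSnapshot <- function(triples, semtypes, dateLabel) {
  tr <- as.data.table(triples)
  if (nrow(tr) == 0L) stop("cannot build a snapshot from an empty triple set")
  if (!"negative" %in% names(tr)) tr[, negative := startsWith(predicate, "NEG")]
  if (!"count" %in% names(tr)) tr[, count := 1L]
  typed <- names(semtypes)[lengths(semtypes) > 0L]
  nDroppedConcepts <- sum(lengths(semtypes) == 0L)
  keep <- tr$subject %in% typed & tr$object %in% typed
  if (any(!keep))
    lbdLog("dropped %d triple(s) with untyped endpoint(s)", sum(!keep))
  if (nDroppedConcepts > 0L)
    lbdLog("dropped %d concept(s) without semantic types", nDroppedConcepts)
  tr <- tr[keep]
  if (nrow(tr) == 0L) stop("no triples survive endpoint typing")
  ep <- sort(unique(c(tr$subject, tr$object)))
  st <- lapply(semtypes[ep], function(v) sort(unique(v)))
  tr <- tr[, .(count = as.integer(sum(count))), by = .(subject, predicate, object, negative)]
  setcolorder(tr, c("subject", "predicate", "object", "count", "negative"))
  setkey(tr, subject, predicate, object)
  new("KnowledgeSnapshot",
    dateLabel = dateLabel,
    triples = tr[],
    semtypes = st,
    relationInventory = sort(unique(tr$predicate))
  )
}

# internal: re-derive inventories after a filter removed triples
rebuildSnapshot <- function(snapshot, newTriples) {
  if (nrow(newTriples) == 0L) {
    return(new("KnowledgeSnapshot",
      dateLabel = snapshot@dateLabel,
      triples = emptyTriples(),
      semtypes = structure(list(), names = character()),
      relationInventory = character()
    ))
  }
  buildSnapshot(newTriples, snapshot@semtypes, snapshot@dateLabel)
}

#' @rdname KnowledgeSnapshot-class
#' @export
setMethod("dateLabel", "KnowledgeSnapshot", function(x) x@dateLabel)

#' @rdname KnowledgeSnapshot-class
#' @export
setMethod("triples", "KnowledgeSnapshot", function(x) copy(x@triples))

#' @rdname KnowledgeSnapshot-class
#' @export
setMethod("semTypes", "KnowledgeSnapshot", function(x) x@semtypes)

#' @rdname KnowledgeSnapshot-class
#' @export
setMethod("relationInventory", "KnowledgeSnapshot", function(x) x@relationInventory)

#' @rdname KnowledgeSnapshot-class
#' @export
setMethod("conceptIds", "KnowledgeSnapshot", function(x) names(x@semtypes))

#' @rdname outDegree
#' @export
setMethod("outDegree", "KnowledgeSnapshot", function(x) {
  od <- structure(integer(length(x@semtypes)), names = names(x@semtypes))
  if (nrow(x@triples)) {
    d <- unique(x@triples[, .(subject, object)])[, .N, by = subject]
    od[d$subject] <- d$N
  }
  od
})

#' @rdname knownPairs
#' @export
setMethod("knownPairs", "KnowledgeSnapshot", function(x) {
  if (nrow(x@triples) == 0L)
    return(data.table(source = character(), target = character()))
  kp <- unique(x@triples[, .(source = subject, target = object)])
  setkey(kp, source, target)
  kp[]
})

setMethod("show", "KnowledgeSnapshot", function(object) {
  cat(sprintf(
    "KnowledgeSnapshot '%s': %d concepts, %d triples, %d predicates, %d semantic types\n",
    object@dateLabel, length(object@semtypes), nrow(object@triples),
    length(object@relationInventory),
    length(unique(unlist(object@semtypes, use.names = FALSE)))
  ))
})

#' Number of triples in a snapshot
#' @param x a \code{KnowledgeSnapshot}
#' @export
setMethod("length", "KnowledgeSnapshot", function(x) nrow(x@triples))
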