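#' Merge ISA-related concepts into equivalence classes
#'
#' Hierarchically related concepts make for uninteresting discoveries: if
#' \emph{fish oil} MAY TREAT \emph{Raynaud's disease} and \emph{Raynaud's
#' disease} ISA \emph{Raynaud's phenomenon}, proposing \emph{fish oil} MAY
#' TREAT \emph{Raynaud's phenomenon} is a vocabulary artifact, not hidden
#' knowledge.  Concepts connected by the hierarchical relation (treated as
#' undirected for grouping, since merging is an equivalence operation) are
#' therefore collapsed onto one representative — the lexicographically
#' smallest member id — before discovery.  All other triples are rewritten
#' onto the representatives, ISA triples are deleted, self-loops arising from
#' the rewrite are removed, and duplicate rewritten triples have their counts
#' summed.  The operation is idempotent.
#'
#' @param triples triples \code{data.table} (see [readRRFRelations()]).
#' @param isaLabel predicate naming the hierarchical relation to collapse.
#' @return list with \code{triples} (rewritten table) and \code{mapping}
#'   (named character vector, member id -> class representative, covering
#'   every concept in a non-trivial class).
#' @examples
#' tr <- readRRFRelations(textConnectionPath <- tempfile())
#' @export
mergeIsaClasses <- function(triples, isaLabel = "ISA") {
  tr <- as.data.table(triples)
  isa <- tr[predicate == isaLabel]
  if (nrow(isa) == 0L) {
    return(list(triples = copy(tr), mapping = structure(character(), names = character())))
  }
  g <- igraph::graph_from_data_frame(
    unique(isa[, .(subject, object)]), directed = FALSE
  )
  comp <- igraph::components(g)
  member <- names(comp$membership)
  rep_ <- vapply(
    split(member, comp$membership),
    function(m) min(m),
    ""
  )
  mapping <- rep_[as.character(comp$membership)]
  names(mapping) <- member

  out <- tr[predicate != isaLabel]
  subjIdx <- match(out$subject, names(mapping))
  objIdx <- match(out$object, names(mapping))
  out[, subject := ifelse(is.na(subjIdx), subject, mapping[subjIdx])]
  out[, object := ifelse(is.na(objIdx), object, mapping[objIdx])]
  out <- out[subject != object]
  out <- out[, .(count = sum(count)), by = .(subject, predicate, object, negative)]
  setcolorder(out, c("subject", "predicate", "object", "count", "negative"))
  setkey(out, subject, predicate, object)
  list(triples = out[], mapping = mapping)
}

#' Propagate an ISA class mapping to a semantic-type assignment
#'
#' The merged class keeps the union of its members' semantic types, so no
#' typing evidence is lost for the feature stage.
#'
#' @param semtypes named list, concept id -> character vector of types.
#' @param mapping member -> representative map from [mergeIsaClasses()].
#' @return named list over representatives and unmapped concepts.
#' @export
mergeSemTypes <- function(semtypes, mapping) {
  if (length(mapping) == 0L) return(semtypes)
  ids <- names(semtypes)
  tgt <- ifelse(ids %in% names(mapping), mapping[ids], ids)
  merged <- lapply(split(seq_along(ids), tgt), function(ix) {
    sort(unique(unlist(semtypes[ix], use.names = FALSE)))
  })
  merged[order(names(merged))]
}
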