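#' Filtering configuration
#'
#' Bundles the thresholds of the three filtering families applied before
#' discovery, plus the optional semantic-type restriction:
#' \itemize{
#'   \item minimum relation frequency — infrequent (often disused) relations
#'     are removed; the default of 10 is the threshold that reduces a full
#'     metathesaurus release to a few dozen usable relation labels;
#'   \item relation blacklist and negated-predication removal — relations
#'     that cannot yield interesting single-step discoveries (e.g.
#'     HAS_PRECISE_INGREDIENT) and negative relations (NEG_TREATS);
#'   \item high-outdegree removal (default 5000) and the automatic linking-term
#'     stoplist (default 10000) — both remove promiscuous terms of the
#'     \emph{clinical trial} kind.
#' }
#' Boundary semantics follow the wording: "exceeding"/"more than" are strict,
#' "minimum frequency of 10" is inclusive.
#'
#' @param minRelFreq keep triples with \code{count >= minRelFreq}.
#' @param outdegreeMax remove concepts with outdegree \code{> outdegreeMax}.
#' @param ltFreqMax stoplist linking terms linking \code{> ltFreqMax}
#'   candidate pairs in a first-pass closure.
#' @param relationBlacklist predicates to drop.
#' @param dropNegative drop negated predications.
#' @param semtypeRestriction \code{NULL} (off, the default) or a list with
#'   character vectors \code{source} and \code{target} of admissible
#'   semantic types for A and C.
#' @return a validated list of class \code{FilterConfig}.
#' @export
filterConfig <- function(minRelFreq = 10L, outdegreeMax = 5000L,
                         ltFreqMax = 10000L, relationBlacklist = character(),
                         dropNegative = TRUE, semtypeRestriction = NULL) {
  stopifnot(
    length(minRelFreq) == 1L, minRelFreq >= 0, minRelFreq == as.integer(minRelFreq),
    length(outdegreeMax) == 1L, outdegreeMax >= 0, outdegreeMax == as.integer(outdegreeMax),
    length(ltFreqMax) == 1L, ltFreqMax >= 0, ltFreqMax == as.integer(ltFreqMax),
    is.character(relationBlacklist), is.logical(dropNegative)
  )
  if (!is.null(semtypeRestriction))
    stopifnot(is.character(semtypeRestriction$source), is.character(semtypeRestriction$target))
  structure(
    list(
      minRelFreq = as.integer(minRelFreq),
      outdegreeMax = as.integer(outdegreeMax),
      ltFreqMax = as.integer(ltFreqMax),
      relationBlacklist = relationBlacklist,
      dropNegative = isTRUE(dropNegative),
      semtypeRestriction = semtypeRestriction
    ),
    class = "FilterConfig"
  )
}

#' Drop infrequent relation triples
#'
#' Keeps triples whose occurrence count is at least \code{minRelFreq}
#' (boundary-inclusive) and recomputes the relation inventory from the
#' survivors.
#'
#' @param snapshot a \code{KnowledgeSnapshot}.
#' @param minRelFreq minimum occurrence count.
#' @return filtered \code{KnowledgeSnapshot} (the input is untouched).
#' @export
applyMinFrequency <- function(snapshot, minRelFreq = 10L) {
  rebuildSnapshot(snapshot, triples(snapshot)[count >= minRelFreq])
}

#' Drop blacklisted and negated relations
#'
#' @param snapshot a \code{KnowledgeSnapshot}.
#' @param blacklist predicates to remove; entries absent from the snapshot's
#'   inventory trigger a warning, not an error.
#' @param dropNegative also remove negated predications.
#' @return filtered \code{KnowledgeSnapshot}.
#' @export
applyRelationBlacklist <- function(snapshot, blacklist = character(),
                                   dropNegative = TRUE) {
  missing <- setdiff(blacklist, relationInventory(snapshot))
  if (length(missing))
    warning("blacklist entries not in relation inventory: ",
            paste(missing, collapse = ", "))
  tr <- triples(snapshot)
  keep <- !(tr$predicate %in% blacklist)
  if (dropNegative) keep <- keep & !tr$negative
  rebuildSnapshot(snapshot, tr[keep])
}

#' Remove high-outdegree concepts
#'
#' Concepts whose outdegree (distinct out-neighbours) strictly exceeds
#' \code{outdegreeMax} are removed together with all incident triples.  The
#' filter is applied once: degrees are computed on the input snapshot and not
#' cascaded after removal.
#'
#' @param snapshot a \code{KnowledgeSnapshot}.
#' @param outdegreeMax maximum admissible outdegree.
#' @return filtered \code{KnowledgeSnapshot}.
#' @export
applyOutdegreeFilter <- function(snapshot, outdegreeMax = 5000L) {
  od <- outDegree(snapshot)
  drop <- names(od)[od > outdegreeMax]
  if (length(drop) == 0L) return(rebuildSnapshot(snapshot, triples(snapshot)))
  lbdLog("outdegree filter removes %d concept(s)", length(drop))
  tr <- triples(snapshot)
  rebuildSnapshot(snapshot, tr[!(subject %in% drop) & !(object %in% drop)])
}

#' Build the automatic linking-term stoplist
#'
#' Runs a first-pass A-B-C closure with no stoplist and counts, for every
#' linking term B, the number of distinct proposed (A, C) pairs it links.
#' Terms linking strictly more than \code{ltFreqMax} pairs are returned:
#' these are the promiscuous \emph{clinical trial}-like concepts whose
#' two-step paths carry no information.  The closure should then be re-run
#' with this stoplist (see [abcClosure()]), which excludes its members from
#' the B role only — they may still appear as A or C.
#'
#' @param snapshot a filtered \code{KnowledgeSnapshot}.
#' @param ltFreqMax maximum admissible linking count.
#' @return character vector of stoplisted concept ids (possibly empty).
#' @export
buildLinkingStoplist <- function(snapshot, ltFreqMax = 10000L) {
  if (length(snapshot) == 0L) return(character())
  firstPass <- abcClosure(snapshot, stoplist = character())
  lw <- unique(linkWitnesses(firstPass)[, .(source, target, b)])
  cnt <- lw[, .N, by = b]
  sort(cnt[N > ltFreqMax]$b)
}

#' Restrict candidate pairs by source/target semantic type
#'
#' Optional filter keeping only pairs whose source has at least one type in
#' the restriction's source set and whose target has at least one type in the
#' target set (e.g. disease sources with chemical/drug or gene targets).  Off
#' by default in the pipeline because it can shrink gold standards to
#' unusable sizes.
#'
#' @param candidates a \code{CandidateSet}.
#' @param restriction list with character vectors \code{source}, \code{target}.
#' @param semtypes named list of per-concept semantic types.
#' @return filtered \code{CandidateSet}.
#' @export
applySemtypeRestriction <- function(candidates, restriction, semtypes) {
  p <- candidatePairs(candidates)
  if (nrow(p) == 0L) return(candidates)
  okA <- vapply(semtypes[p$source], function(t) any(t %in% restriction$source), NA)
  okC <- vapply(semtypes[p$target], function(t) any(t %in% restriction$target), NA)
  keep <- !is.na(okA) & !is.na(okC) & okA & okC
  subsetCandidates(candidates, which(keep))
}

#' Apply the full filtering pipeline
#'
#' Order: minimum relation frequency, relation blacklist (incl. negated
#' predications), outdegree filter, then the closure-based linking-term
#' stoplist — cheap per-triple filters before the expensive one.
#'
#' @param snapshot a \code{KnowledgeSnapshot}.
#' @param config a [filterConfig()].
#' @return list with the filtered \code{snapshot} and the \code{stoplist}.
#' @export
applyFilters <- function(snapshot, config = filterConfig()) {
  s <- applyMinFrequency(snapshot, config$minRelFreq)
  s <- applyRelationBlacklist(s, config$relationBlacklist, config$dropNegative)
  s <- applyOutdegreeFilter(s, config$outdegreeMax)
  stoplist <- buildLinkingStoplist(s, config$ltFreqMax)
  list(snapshot = s, stoplist = stoplist)
}
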