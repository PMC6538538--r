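#' @import methods
#' @import data.table
#' @importFrom Matrix sparseMatrix
NULL

setOldClass(c("data.table", "data.frame"))

#' KnowledgeSnapshot: a dated store of directed relation triples
#'
#' A snapshot holds the concept-relation graph extracted from one release of
#' a knowledge source (a metathesaurus release, or a predication database cut
#' at a date).  Triples are directed \code{subject -> object} edges labelled
#' with a predicate and an occurrence count; every endpoint carries a
#' non-empty set of semantic types.
#'
#' @slot dateLabel ordinal snapshot tag, e.g. \code{"date1"}.
#' @slot triples \code{data.table} with columns \code{subject},
#'   \code{predicate}, \code{object}, \code{count} (integer occurrence
#'   frequency) and \code{negative} (logical, negated predications).
#' @slot semtypes named list mapping concept id to a character vector of
#'   semantic-type identifiers; names are exactly the snapshot's concepts.
#' @slot relationInventory ordered (lexicographic) character vector of the
#'   predicates present in \code{triples}.
#'
#' @seealso [buildSnapshot()], [knownPairs()], [abcClosure()]
#' @export
setClass("KnowledgeSnapshot",
  representation(
    dateLabel         = "character",
    triples           = "data.table",
    semtypes          = "list",
    relationInventory = "character"
  )
)

setValidity("KnowledgeSnapshot", function(object) {
  tr <- object@triples
  need <- c("subject", "predicate", "object", "count", "negative")
  if (!all(need %in% names(tr)))
    return(sprintf("triples must have columns %s", paste(need, collapse = ", ")))
  ids <- names(object@semtypes)
  if (nrow(tr) > 0L) {
    ep <- unique(c(tr$subject, tr$object))
    if (!all(ep %in% ids))
      return("every triple endpoint must be a concept with semantic types")
    if (!all(tr$predicate %in% object@relationInventory))
      return("every predicate must appear in the relation inventory")
  }
  if (length(ids) && any(lengths(object@semtypes) == 0L))
    return("all concepts must have a non-empty semantic-type set")
  if (length(object@dateLabel) != 1L)
    return("dateLabel must be a single string")
  TRUE
})

#' CandidateSet: proposed hidden-knowledge pairs with their linking terms
#'
#' The result of the A-B-C closure: every ordered pair (A, C) connected by at
#' least one directed two-step path A -> B -> C but by no direct triple.
#'
#' @slot pairs \code{data.table} with columns \code{source}, \code{target},
#'   \code{nLinkingTerms}, sorted lexicographically by (source, target).
#' @slot links \code{data.table} of path witnesses with columns
#'   \code{source}, \code{target}, \code{b}, \code{relAB}, \code{relBC}.
#' @slot dateLabel label of the generating snapshot.
#'
#' @seealso [abcClosure()], [featurizeBatch()]
#' @export
setClass("CandidateSet",
  representation(
    pairs     = "data.table",
    links     = "data.table",
    dateLabel = "character"
  )
)

setValidity("CandidateSet", function(object) {
  if (!all(c("source", "target", "nLinkingTerms") %in% names(object@pairs)))
    return("pairs must have columns source, target, nLinkingTerms")
  if (!all(c("source", "target", "b", "relAB", "relBC") %in% names(object@links)))
    return("links must have columns source, target, b, relAB, relBC")
  if (nrow(object@pairs) && any(object@pairs$source == object@pairs$target))
    return("candidate pairs must have source != target")
  if (nrow(object@pairs) && any(object@pairs$nLinkingTerms < 1L))
    return("every candidate pair needs at least one linking term")
  TRUE
})

#' FeatureLayout: slot assignment for hidden-knowledge feature vectors
#'
#' Fixes the meaning of every column of a feature matrix:
#' slot 1 is the number of linking terms, followed by three equally sized
#' semantic-type blocks (source A, target C, linking terms) and one block of
#' relation slots.  Total length is \code{1 + 3 * nSemtypes + nRelations}.
#'
#' @slot semTypes lexicographically ordered semantic-type identifiers.
#' @slot relations lexicographically ordered predicate labels.
#'
#' @seealso [buildLayout()], [featurizeBatch()]
#' @export
setClass("FeatureLayout",
  representation(semTypes = "character", relations = "character")
)

setValidity("FeatureLayout", function(object) {
  if (length(object@semTypes) == 0L) return("semantic-type inventory is empty")
  if (length(object@relations) == 0L) return("relation inventory is empty")
  if (is.unsorted(object@semTypes) || anyDuplicated(object@semTypes))
    return("semTypes must be sorted and unique")
  if (is.unsorted(object@relations) || anyDuplicated(object@relations))
    return("relations must be sorted and unique")
  TRUE
})

#' PageRankWeights: stationary random-walk weights over snapshot concepts
#'
#' @slot weights named numeric vector of per-concept probability mass,
#'   summing to 1 over the snapshot's vertices.
#' @slot damping damping factor in (0, 1).
#' @slot tol L1 convergence tolerance used.
#' @slot iterations number of power iterations run.
#' @slot converged whether the L1 change fell below \code{tol}.
#'
#' @seealso [computePageRank()]
#' @export
setClass("PageRankWeights",
  representation(
    weights    = "numeric",
    damping    = "numeric",
    tol        = "numeric",
    iterations = "integer",
    converged  = "logical"
  )
)

setValidity("PageRankWeights", function(object) {
  if (is.null(names(object@weights))) return("weights must be named by concept id")
  if (abs(sum(object@weights) - 1) > 1e-9) return("weights must sum to 1")
  if (object@damping <= 0 || object@damping >= 1) return("damping must be in (0,1)")
  TRUE
})

#' AnomalyModel: fitted anomaly/novelty detector over feature vectors
#'
#' Virtual parent of [IsolationForestModel-class] and
#' [OneClassSVMModel-class].
#'
#' @slot params list of fitting parameters, recorded for provenance.
#' @slot nFeatures width of the feature layout the model was fitted on.
#' @export
setClass("AnomalyModel",
  representation("VIRTUAL", params = "list", nFeatures = "integer")
)

#' IsolationForestModel: ensemble of random isolation trees
#'
#' @slot trees list of flattened tree structures (see [fitIsolationForest()]).
#' @slot sampleSize subsample size per tree.
#' @slot nTrees number of trees.
#' @slot seed RNG seed the forest was grown with.
#' @slot contamination assumed training outlier fraction in [0, 0.5].
#' @slot threshold score threshold implied by \code{contamination}.
#' @slot trainScores anomaly scores of the training rows.
#' @export
setClass("IsolationForestModel",
  contains = "AnomalyModel",
  representation(
    trees         = "list",
    sampleSize    = "integer",
    nTrees        = "integer",
    seed          = "integer",
    contamination = "numeric",
    threshold     = "numeric",
    trainScores   = "numeric"
  )
)

setValidity("IsolationForestModel", function(object) {
  if (object@nTrees < 1L) return("need at least one tree")
  if (object@contamination < 0 || object@contamination > 0.5)
    return("contamination must be in [0, 0.5]")
  TRUE
})

#' OneClassSVMModel: one-class support vector machine boundary
#'
#' Wraps a radial-basis one-class SVM fitted on the normal
#' (uninteresting) pairs only; new vectors are classified as similar or
#' different to that training set.
#'
#' @slot fit the underlying fitted SVM object.
#' @export
setClass("OneClassSVMModel",
  contains = "AnomalyModel",
  representation(fit = "ANY")
)
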