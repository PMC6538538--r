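#' @rdname KnowledgeSnapshot-class
#' @param object,x a \code{KnowledgeSnapshot}
#' @export
setGeneric("dateLabel", function(x) standardGeneric("dateLabel"))

#' @rdname KnowledgeSnapshot-class
#' @export
setGeneric("triples", function(x) standardGeneric("triples"))

#' @rdname KnowledgeSnapshot-class
#' @export
setGeneric("semTypes", function(x) standardGeneric("semTypes"))

#' @rdname KnowledgeSnapshot-class
#' @export
setGeneric("relationInventory", function(x) standardGeneric("relationInventory"))

#' @rdname KnowledgeSnapshot-class
#' @export
setGeneric("conceptIds", function(x) standardGeneric("conceptIds"))

#' Distinct out-neighbour count per concept
#'
#' Outdegree is the number of distinct out-neighbours in the relation graph,
#' ignoring triple multiplicity, matching the graph-degree reading used by
#' the high-outdegree filter.
#'
#' @param x a \code{KnowledgeSnapshot}
#' @return named integer vector over all snapshot concepts (0 for sinks).
#' @export
setGeneric("outDegree", function(x) standardGeneric("outDegree"))

#' Known direct pairs of a snapshot
#'
#' All ordered (subject, object) pairs carrying at least one triple.
#'
#' @param x a \code{KnowledgeSnapshot}
#' @return \code{data.table} with columns \code{source}, \code{target}.
#' @export
setGeneric("knownPairs", function(x) standardGeneric("knownPairs"))

#' @rdname CandidateSet-class
#' @param x a \code{CandidateSet}
#' @export
setGeneric("candidatePairs", function(x) standardGeneric("candidatePairs"))

#' @rdname CandidateSet-class
#' @export
setGeneric("linkWitnesses", function(x) standardGeneric("linkWitnesses"))

#' @rdname FeatureLayout-class
#' @param x a \code{FeatureLayout}
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname FeatureLayout-class
#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))

#' Anomaly scores for feature vectors
#'
#' Higher scores mean more anomalous.  For the isolation forest the score is
#' the standard \code{2^(-E[h]/c(psi))} path-length statistic; for the
#' one-class SVM it is the negated signed decision value, so that vectors
#' outside the fitted boundary score above 0.
#'
#' @param model a fitted [AnomalyModel-class]
#' @param x numeric matrix (dense or sparse) whose width matches the model
#' @return numeric vector of scores, one per row of \code{x}
#' @export
setGeneric("anomalyScores", function(model, x) standardGeneric("anomalyScores"))

#' Decision flags for feature vectors
#'
#' \code{TRUE} where the model's native threshold flags the vector as
#' anomalous (isolation forest: score at or above the contamination-implied
#' training threshold; one-class SVM: classified different from training).
#'
#' @inheritParams anomalyScores
#' @return logical vector, one per row of \code{x}
#' @export
setGeneric("anomalyFlags", function(model, x) standardGeneric("anomalyFlags"))
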