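#' Score and rank candidate pairs by anomaly
#'
#' Applies a fitted model to a feature matrix and returns the full ranking,
#' most anomalous first, with ties broken by pair id (stable, reproducible
#' output).  The \code{selected} column applies the model's native decision
#' threshold (see [anomalyFlags()]).
#'
#' @param model a fitted [AnomalyModel-class].
#' @param x feature matrix whose rownames are \code{"source|target"} pair
#'   ids, as produced by [featurizeBatch()].
#' @return \code{data.table} with columns \code{source}, \code{target},
#'   \code{score}, \code{selected}, sorted by decreasing score.
#' @export
scorePairs <- function(model, x) {
  if (nrow(x) == 0L)
    return(data.table(source = character(), target = character(),
                      score = numeric(), selected = logical()))
  if (is.null(rownames(x))) stop("feature matrix must carry pair-id rownames")
  ids <- tstrsplit(rownames(x), "|", fixed = TRUE)
  ranked <- data.table(
    source = ids[[1]], target = ids[[2]],
    score = anomalyScores(model, x),
    selected = anomalyFlags(model, x)
  )
  ranked[order(-score, source, target)]
}

#' Select the anomalous subset of a ranking
#'
#' The selected subset is what the evaluation stage scores as the system
#' output.  Policies: \code{"native"} uses the model's own decision
#' threshold (the \code{selected} flags); \code{"topk"} takes the \code{k}
#' highest-scoring pairs.
#'
#' @param ranked ranking from [scorePairs()].
#' @param policy \code{"native"} (default) or \code{"topk"}.
#' @param k subset size for \code{"topk"}.
#' @return \code{data.table} with columns \code{source}, \code{target}.
#' @export
selectAnomalies <- function(ranked, policy = c("native", "topk"), k = NULL) {
  policy <- match.arg(policy)
  out <- switch(policy,
    native = ranked[selected == TRUE],
    topk = {
      stopifnot(!is.null(k), k >= 0)
      head(ranked, k)
    }
  )
  out[, .(source, target)]
}

#' Write a ranking as TSV
#'
#' @param ranked ranking from [scorePairs()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRanking <- function(ranked, path) {
  fwrite(ranked, path, sep = "\t")
  invisible(path)
}
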