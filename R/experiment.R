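#' Run a full three-date timeslice experiment
#'
#' End-to-end orchestration of the discovery-and-re-ranking protocol:
#' \enumerate{
#'   \item filter all three snapshots identically (minimum frequency,
#'     relation blacklist, outdegree, linking-term stoplist);
#'   \item generate hidden knowledge from date1 and annotate training
#'     outliers from date2 ([labelTrainingOutliers()]);
#'   \item fit the isolation forest unsupervised on all date1 candidate
#'     vectors, with contamination set to the observed date2-confirmed
#'     outlier fraction, and the one-class SVM on the normal vectors only
#'     with \code{nu = max(outlierFraction, 0.01)};
#'   \item generate hidden knowledge from date2, score and select it with
#'     each model;
#'   \item evaluate the unranked candidate set ("orig") and each selected
#'     subset against the (date2, date3) gold standard.
#' }
#' Training features use PageRank weights from the date1 graph, test
#' features from the date2 graph, over a shared layout combining both
#' inventories.  The no-leakage property — date2 candidates are disjoint
#' from date2 known pairs and hence from the date2-confirmed training
#' outliers — holds by construction and is asserted.
#'
#' @param snap1,snap2,snap3 raw \code{KnowledgeSnapshot}s in date order.
#' @param config a [filterConfig()] applied to all three snapshots.
#' @param forestParams list: \code{nTrees}, \code{sampleSize}, \code{seed}.
#' @param svmParams list: optional \code{nu}, \code{gamma},
#'   \code{memoryBudget} overrides.
#' @param models character subset of \code{c("iso", "one")}.
#' @param pagerankParams list: \code{damping}, \code{tol}, \code{maxIter}.
#' @param keepRankings return the full per-model rankings in the report.
#' @return a report list with evaluations (\code{orig}, and per requested
#'   model), set sizes, provenance (seeds, thresholds, filter order), and
#'   optionally rankings.
#' @export
runTimesliceExperiment <- function(snap1, snap2, snap3,
                                   config = filterConfig(),
                                   forestParams = list(nTrees = 100L, sampleSize = 256L, seed = 1L),
                                   svmParams = list(),
                                   models = c("iso", "one"),
                                   pagerankParams = list(damping = 0.85, tol = 1e-8, maxIter = 200L),
                                   keepRankings = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  labs <- c(dateLabel(snap1), dateLabel(snap2), dateLabel(snap3))
  if (anyDuplicated(labs) || is.unsorted(labs))
    stop("snapshots must carry strictly increasing date labels")

  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "lbdResourceError")) stop(e)
      stop(sprintf("[stage: %s] %s", what, conditionMessage(e)), call. = FALSE)
    })
  }

  f1 <- stage("filter date1", applyFilters(snap1, config))
  f2 <- stage("filter date2", applyFilters(snap2, config))
  f3 <- stage("filter date3", applyFilters(snap3, config))

  hk1 <- stage("closure date1", abcClosure(f1$snapshot, f1$stoplist))
  hk2 <- stage("closure date2", abcClosure(f2$snapshot, f2$stoplist))
  if (!is.null(config$semtypeRestriction)) {
    hk1 <- applySemtypeRestriction(hk1, config$semtypeRestriction, semTypes(f1$snapshot))
    hk2 <- applySemtypeRestriction(hk2, config$semtypeRestriction, semTypes(f2$snapshot))
  }

  labels <- stage("training labels", labelTrainingOutliers(hk1, f2$snapshot))

  # no-leakage assertions: test candidates are unknown at date2 by
  # construction, hence disjoint from the date2-confirmed training outliers
  kp2 <- knownPairs(f2$snapshot)
  if (nrow(fintersect(candidatePairs(hk2)[, .(source, target)], kp2)) != 0L)
    stop("leakage: date2 candidates intersect date2 known pairs")
  if (nrow(fintersect(labels$outlier, candidatePairs(hk2)[, .(source, target)])) != 0L)
    stop("leakage: training outlier labels intersect test candidates")

  layout <- stage("layout", combineLayouts(buildLayout(f1$snapshot), buildLayout(f2$snapshot)))
  pr1 <- stage("pagerank date1", do.call(computePageRank, c(list(f1$snapshot), pagerankParams)))
  pr2 <- stage("pagerank date2", do.call(computePageRank, c(list(f2$snapshot), pagerankParams)))
  X1 <- stage("featurize date1", featurizeBatch(hk1, layout, pr1, semTypes(f1$snapshot)))
  X2 <- stage("featurize date2", featurizeBatch(hk2, layout, pr2, semTypes(f2$snapshot)))

  gold <- stage("gold standard", buildGoldStandard(f2$snapshot, f3$snapshot))

  testPairs <- candidatePairs(hk2)[, .(source, target)]
  evaluations <- list(orig = evaluateF1(testPairs, gold))
  rankings <- list()
  provenance <- list(
    dateLabels = labs,
    filterOrder = c("minFrequency", "relationBlacklist", "outdegree", "stoplist"),
    config = config[setdiff(names(config), "semtypeRestriction")],
    semtypeRestriction = !is.null(config$semtypeRestriction),
    stoplistSizes = c(date1 = length(f1$stoplist), date2 = length(f2$stoplist)),
    outlierFraction = labels$outlierFraction,
    pagerank = pagerankParams
  )

  if ("iso" %in% models) {
    fp <- utils::modifyList(list(nTrees = 100L, sampleSize = 256L, seed = 1L), forestParams)
    iso <- stage("fit isolation forest", fitIsolationForest(
      X1, nTrees = fp$nTrees, sampleSize = fp$sampleSize, seed = fp$seed,
      contamination = min(labels$outlierFraction, 0.5)))
    rankedIso <- stage("score isolation forest", scorePairs(iso, X2))
    evaluations$iso <- evaluateF1(selectAnomalies(rankedIso), gold)
    provenance$forest <- iso@params
    provenance$forest$threshold <- iso@threshold
    if (keepRankings) rankings$iso <- rankedIso
  }

  if ("one" %in% models) {
    sp <- utils::modifyList(
      list(nu = max(labels$outlierFraction, 0.01), gamma = NULL,
           memoryBudget = 4 * 1024^3),
      svmParams)
    Xn <- X1[!labels$isOutlier, , drop = FALSE]
    one <- stage("fit one-class SVM", fitOneClass(
      Xn, nu = sp$nu, gamma = sp$gamma, memoryBudget = sp$memoryBudget))
    rankedOne <- stage("score one-class SVM", scorePairs(one, X2))
    evaluations$one <- evaluateF1(selectAnomalies(rankedOne), gold)
    provenance$svm <- one@params
    if (keepRankings) rankings$one <- rankedOne
  }

  report <- list(
    sizes = list(
      hkTrain = length(hk1), hkTest = length(hk2), gs = nrow(gold),
      trainingOutliers = nrow(labels$outlier),
      hkIso = if ("iso" %in% models) evaluations$iso$hkSize else NULL,
      hkOne = if ("one" %in% models) evaluations$one$hkSize else NULL
    ),
    evaluations = evaluations,
    provenance = provenance
  )
  if (keepRankings) report$rankings <- rankings
  report
}

#' Serialise an experiment report to JSON
#'
#' Deterministic serialisation (fixed precision, no pretty-printing
#' variation), so identical configurations and seeds produce byte-identical
#' report files.
#'
#' @param report list from [runTimesliceExperiment()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(report, path) {
  report$rankings <- NULL
  writeLines(reportJSON(report), path)
  invisible(path)
}

reportJSON <- function(report) {
  report$rankings <- NULL
  report$evaluations <- lapply(report$evaluations, unclass)
  jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
}
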