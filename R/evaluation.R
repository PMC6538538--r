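#' Build a timeslicing gold standard
#'
#' The gold standard for a (date2, date3) window is the set of ordered
#' concept pairs that carry a triple in the later snapshot but none in the
#' earlier one — knowledge that actually appeared during the window.  Both
#' snapshots must have gone through the same ISA merging and filtering
#' regime, otherwise vocabulary churn between releases floods the gold set
#' with artifacts.
#'
#' @param earlier,later \code{KnowledgeSnapshot}s with distinct date labels.
#' @return \code{data.table} of pairs (\code{source}, \code{target}) with a
#'   \code{window} attribute \code{c(earlier, later)} date labels.
#' @export
buildGoldStandard <- function(earlier, later) {
  if (identical(dateLabel(earlier), dateLabel(later)))
    stop("gold standard needs two distinct snapshot dates")
  gold <- fsetdiff(knownPairs(later), knownPairs(earlier))
  setkey(gold, source, target)
  setattr(gold, "window", c(dateLabel(earlier), dateLabel(later)))
  gold[]
}

#' Annotate training candidates as normal or outlier
#'
#' The anomaly model is built from hidden knowledge generated up to date1,
#' with outliers annotated from information up to date2: a candidate pair is
#' an outlier (interesting, by the timeslice's lights) exactly when it became
#' known by date2.  The partition is exhaustive and disjoint.
#'
#' @param candidates \code{CandidateSet} generated from the date1 snapshot.
#' @param snapshotLater the (identically filtered) date2 snapshot.
#' @return list with \code{isOutlier} (logical aligned with
#'   \code{candidatePairs(candidates)}), \code{normal} and \code{outlier}
#'   pair tables, and \code{outlierFraction}.
#' @export
labelTrainingOutliers <- function(candidates, snapshotLater) {
  p <- candidatePairs(candidates)
  kp <- knownPairs(snapshotLater)
  isOut <- !is.na(kp[p, on = c("source", "target"), which = TRUE])
  list(
    isOutlier = isOut,
    normal = p[!isOut, .(source, target)],
    outlier = p[isOut, .(source, target)],
    outlierFraction = if (nrow(p)) mean(isOut) else 0
  )
}

#' Precision, recall and F1 of a predicted pair set
#'
#' Both sets use the ordered-pair convention.  Precision is tp/|predicted|
#' (0 for an empty prediction), recall is tp/|gold|, and F1 is their
#' harmonic mean (equivalently \code{2*tp/(|predicted|+|gold|)}), 0 when
#' undefined.  An empty gold standard makes the evaluation meaningless and
#' is an error.
#'
#' @param predicted \code{data.table}/data.frame with columns \code{source},
#'   \code{target}.
#' @param gold gold standard pairs (same convention).
#' @return an \code{EvaluationResult} list: \code{tp}, \code{fp}, \code{fn},
#'   \code{precision}, \code{recall}, \code{f1}, \code{hkSize}, \code{gsSize}.
#' @examples
#' p <- data.table::data.table(source = c("a", "b"), target = c("x", "y"))
#' g <- data.table::data.table(source = "a", target = "x")
#' evaluateF1(p, g)
#' @export
evaluateF1 <- function(predicted, gold) {
  gold <- asPairTable(gold)
  if (nrow(gold) == 0L) stop("empty gold standard: evaluation is meaningless")
  predicted <- asPairTable(predicted)
  tp <- nrow(fintersect(predicted, gold))
  hk <- nrow(predicted); gs <- nrow(gold)
  precision <- if (hk > 0L) tp / hk else 0
  recall <- tp / gs
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(
    list(tp = tp, fp = hk - tp, fn = gs - tp,
         precision = precision, recall = recall, f1 = f1,
         hkSize = hk, gsSize = gs),
    class = "EvaluationResult"
  )
}

#' @export
print.EvaluationResult <- function(x, ...) {
  cat(sprintf(
    "EvaluationResult: |HK| %d, |GS| %d, tp %d, P %.4g, R %.4g, F1 %.4g\n",
    x$hkSize, x$gsSize, x$tp, x$precision, x$recall, x$f1
  ))
  invisible(x)
}

#' Paired t-test over per-split F values
#'
#' Classical paired t on the differences \code{fB - fA} across timeslice
#' splits; the default tail is one-sided (is system B better than system
#' A?).  With a positive t statistic the one-sided p is exactly half the
#' two-sided one.
#'
#' @param fA,fB equal-length (>= 2) numeric vectors of per-split F values.
#' @param tail \code{"one.sided"} (default, upper tail of \code{fB - fA}) or
#'   \code{"two.sided"}.
#' @return a \code{SignificanceResult} list: \code{tStatistic}, \code{df},
#'   \code{pValue}, \code{tail}, \code{meanDifference}.
#' @examples
#' pairedTTest(c(0.1, 0.2, 0.3), c(0.15, 0.26, 0.33))
#' @export
pairedTTest <- function(fA, fB, tail = c("one.sided", "two.sided")) {
  tail <- match.arg(tail)
  if (length(fA) != length(fB)) stop("fA and fB must have equal length")
  if (length(fA) < 2L) stop("need at least two splits")
  d <- fB - fA
  if (stats::sd(d) == 0)
    stop("degenerate input: zero-variance differences")
  tt <- stats::t.test(fB, fA, paired = TRUE,
                      alternative = if (tail == "one.sided") "greater" else "two.sided")
  structure(
    list(tStatistic = unname(tt$statistic), df = unname(tt$parameter),
         pValue = tt$p.value, tail = tail, meanDifference = mean(d)),
    class = "SignificanceResult"
  )
}

#' @export
print.SignificanceResult <- function(x, ...) {
  cat(sprintf("SignificanceResult: t = %.4g on %d df, %s p = %.4g\n",
              x$tStatistic, x$df, x$tail, x$pValue))
  invisible(x)
}
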