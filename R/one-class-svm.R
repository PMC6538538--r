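#' Fit a one-class SVM on normal (uninteresting) pairs
#'
#' Novelty-detection protocol: only the large class — hidden pairs labelled
#' uninteresting by the timeslice annotation — is used for training, and new
#' vectors are classified as similar or different to that set.  A
#' radial-basis one-class SVM is fitted on the dense training matrix;
#' \code{nu} bounds the fraction of training points outside the boundary and
#' defaults to 0.01, and \code{gamma} defaults to
#' \code{1 / (nFeatures * var(x))} (inverse feature count scaled by overall
#' feature variance).  Feature values are not standardised: the PageRank
#' magnitudes are the weighting signal.
#'
#' One-class SVMs need the full dense training matrix in memory (at
#' database scale this can run to hundreds of gigabytes), so the projected
#' matrix size is checked against \code{memoryBudget} first and a resource
#' error naming the matrix size is raised instead of crashing mid-fit.
#'
#' @param x numeric matrix (dense or sparse) of NORMAL training vectors.
#' @param nu upper bound on the training outlier fraction, in (0, 1).
#' @param gamma RBF kernel width; \code{NULL} for the variance-scaled default.
#' @param memoryBudget maximum admissible dense training-matrix size in
#'   bytes (default 4 GiB).
#' @return a [OneClassSVMModel-class].
#' @export
fitOneClass <- function(x, nu = 0.01, gamma = NULL, memoryBudget = 4 * 1024^3) {
  bytes <- as.numeric(nrow(x)) * ncol(x) * 8
  if (bytes > memoryBudget)
    lbdResourceError(sprintf(
      "one-class SVM training matrix %d x %d (%.1f GiB dense) exceeds the %.1f GiB memory budget",
      nrow(x), ncol(x), bytes / 1024^3, memoryBudget / 1024^3))
  X <- as.matrix(x)
  if (nrow(X) < 2L) stop("one-class SVM needs at least two training vectors")
  v <- stats::var(as.vector(X))
  if (!is.finite(v) || v <= 0)
    stop("degenerate training set: all feature values identical (zero variance)")
  if (is.null(gamma)) gamma <- 1 / (ncol(X) * v)
  stopifnot(nu > 0, nu < 1)
  fit <- tryCatch(
    e1071::svm(X, y = NULL, type = "one-classification", kernel = "radial",
               nu = nu, gamma = gamma, scale = FALSE),
    error = function(e) {
      if (grepl("cannot allocate", conditionMessage(e), ignore.case = TRUE))
        lbdResourceError(sprintf(
          "one-class SVM ran out of memory on a %d x %d matrix: %s",
          nrow(X), ncol(X), conditionMessage(e)))
      stop(e)
    }
  )
  new("OneClassSVMModel",
    fit = fit, nFeatures = ncol(X),
    params = list(nu = nu, gamma = gamma, kernel = "radial"))
}

ocsvmDecision <- function(model, x) {
  X <- as.matrix(x)
  if (ncol(X) != model@nFeatures)
    stop(sprintf("feature width %d does not match the model's %d", ncol(X), model@nFeatures))
  if (nrow(X) == 0L) return(numeric())
  pred <- stats::predict(model@fit, X, decision.values = TRUE)
  as.numeric(attr(pred, "decision.values"))
}

#' @rdname anomalyScores
#' @export
setMethod("anomalyScores", "OneClassSVMModel", function(model, x) {
  # signed margin, negated: positive decision values lie inside the boundary
  -ocsvmDecision(model, x)
})

#' @rdname anomalyFlags
#' @export
setMethod("anomalyFlags", "OneClassSVMModel", function(model, x) {
  ocsvmDecision(model, x) < 0
})

setMethod("show", "OneClassSVMModel", function(object) {
  cat(sprintf(
    "OneClassSVMModel: RBF kernel, nu %.4f, gamma %.4g, %d support vectors\n",
    object@params$nu, object@params$gamma, object@fit$tot.nSV
  ))
})
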