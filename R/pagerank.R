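#' PageRank weights over a snapshot's concept graph
#'
#' Concepts are the vertices and the stored directed relation triples the
#' edges (distinct edges, unweighted — triple multiplicity does not change
#' the walk).  The stationary distribution of the damped random walk gives
#' every concept a numerical weight: important, well-connected concepts
#' accumulate mass, and these weights later fill the semantic-type slots of
#' the feature vectors.
#'
#' Power iteration with uniform teleportation; the mass of dangling vertices
#' (no out-edges) is redistributed uniformly each step.  Iteration stops when
#' the L1 change falls below \code{tol} or after \code{maxIter} steps (a
#' warning is logged if unconverged).
#'
#' @param snapshot non-empty \code{KnowledgeSnapshot}.
#' @param damping damping factor in (0, 1); default 0.85.
#' @param tol L1 convergence tolerance; default 1e-8.
#' @param maxIter iteration cap; default 200.
#' @return a [PageRankWeights-class] over all snapshot concepts.
#' @examples
#' tr <- data.table::data.table(
#'   subject = c("A", "B", "C"), predicate = "rel",
#'   object = c("B", "C", "A"), count = 10L, negative = FALSE
#' )
#' pr <- computePageRank(buildSnapshot(tr, list(A = "t", B = "t", C = "t"), "d1"))
#' pageRankOf(pr)  # each 1/3 on a directed 3-cycle
#' @export
computePageRank <- function(snapshot, damping = 0.85, tol = 1e-8, maxIter = 200L) {
  if (length(snapshot) == 0L) stop("cannot compute PageRank on an empty snapshot")
  stopifnot(damping > 0, damping < 1)
  ids <- conceptIds(snapshot)
  n <- length(ids)
  e <- unique(triples(snapshot)[, .(subject, object)])
  i <- match(e$subject, ids)
  j <- match(e$object, ids)
  A <- sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  odeg <- Matrix::rowSums(A)
  dangling <- odeg == 0
  x <- rep(1 / n, n)
  it <- 0L
  converged <- FALSE
  while (it < maxIter) {
    it <- it + 1L
    contrib <- x / pmax(odeg, 1)
    contrib[dangling] <- 0
    xNew <- as.numeric(damping * Matrix::crossprod(A, contrib)) +
      damping * sum(x[dangling]) / n +
      (1 - damping) / n
    delta <- sum(abs(xNew - x))
    x <- xNew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("PageRank did not converge in %d iterations (L1 change above %g)",
                    maxIter, tol))
  x <- x / sum(x)
  names(x) <- ids
  new("PageRankWeights",
    weights = x, damping = damping, tol = tol,
    iterations = it, converged = converged)
}

#' @rdname PageRankWeights-class
#' @param x a \code{PageRankWeights}
#' @param ids optional concept ids to extract
#' @export
pageRankOf <- function(x, ids = NULL) {
  if (is.null(ids)) x@weights else x@weights[ids]
}

setMethod("show", "PageRankWeights", function(object) {
  cat(sprintf(
    "PageRankWeights: %d concepts, damping %.2f, %d iterations (%s)\n",
    length(object@weights), object@damping, object@iterations,
    if (object@converged) "converged" else "NOT converged"
  ))
})
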