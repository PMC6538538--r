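# Isolation forest: anomalies are points that random axis-parallel splits
# isolate quickly, so short average path lengths over an ensemble of random
# partition trees mark outliers.  Fitting subsamples a fixed number of rows
# per tree, so memory is independent of the candidate-set size.

# average unsuccessful-search depth in a BST of n nodes; the standard
# path-length normaliser
cFactor <- function(n) {
  out <- numeric(length(n))
  out[n == 2] <- 1
  big <- n > 2
  nb <- n[big]
  out[big] <- 2 * (log(nb - 1) + 0.5772156649015329) - 2 * (nb - 1) / nb
  out
}

# grow one isolation tree on dense matrix X (the subsample); returns flat
# parallel arrays: feature (0 = leaf), split, left, right, size
growITree <- function(X, heightLimit) {
  cap <- 2L * nrow(X) + 1L
  feature <- integer(cap); split <- numeric(cap)
  left <- integer(cap); right <- integer(cap); size <- integer(cap)
  nid <- 0L
  recurse <- function(idx, depth) {
    nid <<- nid + 1L
    my <- nid
    if (length(idx) > 1L && depth < heightLimit) {
      sub <- X[idx, , drop = FALSE]
      lo <- apply(sub, 2L, min)
      hi <- apply(sub, 2L, max)
      varying <- which(hi > lo)
      if (length(varying)) {
        f <- varying[sample.int(length(varying), 1L)]
        sp <- stats::runif(1L, lo[f], hi[f])
        goLeft <- sub[, f] < sp
        # runif can hit the boundary; force a proper split
        if (!any(goLeft) || all(goLeft)) goLeft <- sub[, f] <= lo[f]
        feature[my] <<- f
        split[my] <<- sp
        left[my] <<- recurse(idx[goLeft], depth + 1L)
        right[my] <<- recurse(idx[!goLeft], depth + 1L)
        return(my)
      }
    }
    size[my] <<- length(idx)
    my
  }
  recurse(seq_len(nrow(X)), 0L)
  n <- nid
  list(feature = feature[seq_len(n)], split = split[seq_len(n)],
       left = left[seq_len(n)], right = right[seq_len(n)],
       size = size[seq_len(n)])
}

# vectorised descent of all rows of X through one flat tree
treePathLengths <- function(tree, X) {
  node <- rep(1L, nrow(X))
  depth <- integer(nrow(X))
  active <- which(tree$feature[node] > 0L)
  while (length(active)) {
    nd <- node[active]
    f <- tree$feature[nd]
    v <- X[cbind(active, f)]
    node[active] <- ifelse(v < tree$split[nd], tree$left[nd], tree$right[nd])
    depth[active] <- depth[active] + 1L
    active <- active[tree$feature[node[active]] > 0L]
  }
  depth + cFactor(tree$size[node])
}

#' Fit an isolation forest
#'
#' Trains the standard isolation-forest outlier detector on all candidate
#' feature vectors (no labels): each of \code{nTrees} trees (default 100) is
#' grown on a random subsample of \code{sampleSize} rows with uniformly
#' random axis-parallel splits; the anomaly score of a vector is
#' \code{2^(-E[h]/c(sampleSize))} where \code{E[h]} is its average path
#' length, so scores grow towards 1 as isolation gets easier.  Fitting
#' memory depends on \code{sampleSize}, not on the number of candidates.
#'
#' The score threshold implied by \code{contamination} (the assumed training
#' outlier fraction) is recorded so that [anomalyFlags()] flags the
#' most-anomalous \code{contamination} fraction of the training data.
#'
#' @param x numeric matrix (dense or sparse), one row per training vector;
#'   at least two distinct rows are required.
#' @param nTrees number of trees (default 100).
#' @param sampleSize subsample size per tree (default 256, capped at
#'   \code{nrow(x)}).
#' @param seed mandatory RNG seed; the forest is deterministic given it.
#' @param contamination assumed outlier fraction in [0, 0.5].
#' @return an [IsolationForestModel-class].
#' @export
fitIsolationForest <- function(x, nTrees = 100L, sampleSize = 256L, seed,
                               contamination = 0.1) {
  if (missing(seed)) stop("an RNG seed is required for a reproducible forest")
  X <- as.matrix(x)
  if (nrow(X) < 2L || all(apply(X, 2L, function(v) max(v) == min(v))))
    stop("isolation forest needs at least two distinct training vectors")
  stopifnot(contamination >= 0, contamination <= 0.5)
  psi <- as.integer(min(sampleSize, nrow(X)))
  hlim <- as.integer(ceiling(log2(psi)))
  trees <- withSeed(seed, {
    lapply(seq_len(nTrees), function(k) {
      idx <- sample.int(nrow(X), psi)
      growITree(X[idx, , drop = FALSE], hlim)
    })
  })
  model <- new("IsolationForestModel",
    trees = trees, sampleSize = psi, nTrees = as.integer(nTrees),
    seed = as.integer(seed), contamination = contamination,
    threshold = NA_real_, trainScores = numeric(),
    nFeatures = ncol(X),
    params = list(nTrees = as.integer(nTrees), sampleSize = psi,
                  seed = as.integer(seed), contamination = contamination)
  )
  ts <- anomalyScores(model, X)
  model@trainScores <- ts
  model@threshold <- as.numeric(stats::quantile(ts, 1 - contamination, names = FALSE))
  model
}

#' @rdname anomalyScores
#' @export
setMethod("anomalyScores", "IsolationForestModel", function(model, x) {
  X <- as.matrix(x)
  if (nrow(X) == 0L) return(numeric())
  if (ncol(X) != model@nFeatures)
    stop(sprintf("feature width %d does not match the model's %d", ncol(X), model@nFeatures))
  pl <- vapply(model@trees, function(tr) treePathLengths(tr, X), numeric(nrow(X)))
  if (nrow(X) == 1L) pl <- matrix(pl, nrow = 1L)
  avg <- rowMeans(pl)
  2^(-avg / cFactor(model@sampleSize))
})

#' @rdname anomalyFlags
#' @export
setMethod("anomalyFlags", "IsolationForestModel", function(model, x) {
  anomalyScores(model, x) >= model@threshold
})

setMethod("show", "IsolationForestModel", function(object) {
  cat(sprintf(
    "IsolationForestModel: %d trees, subsample %d, contamination %.3f, seed %d\n",
    object@nTrees, object@sampleSize, object@contamination, object@seed
  ))
})

#' Rank the forest's decision points
#'
#' Splits near the roots of the isolation trees are the attributes that
#' separate outliers fastest; inspecting them shows which features the model
#' considers decisive (e.g. "number of linking terms", "A:dsyn").  Counts how
#' often each feature is used as a split at tree depth at most
#' \code{depthCutoff} (root = depth 0) and names the slots via the layout.
#'
#' @param model an [IsolationForestModel-class].
#' @param layout the [FeatureLayout-class] the model was trained with.
#' @param depthCutoff maximum split depth to count (default 2).
#' @return \code{data.table} with columns \code{feature}, \code{count},
#'   most frequent first.
#' @export
inspectDecisionPoints <- function(model, layout, depthCutoff = 2L) {
  if (!is(model, "IsolationForestModel"))
    stop("decision-point inspection requires an isolation forest")
  nm <- featureNames(layout)
  if (length(nm) != model@nFeatures)
    stop("layout width does not match the model")
  counts <- integer(length(nm))
  for (tree in model@trees) {
    depth <- integer(length(tree$feature))
    # children are created after parents, so a forward pass fills depths
    for (i in seq_along(tree$feature)) {
      if (tree$feature[i] > 0L) {
        depth[tree$left[i]] <- depth[i] + 1L
        depth[tree$right[i]] <- depth[i] + 1L
      }
    }
    use <- tree$feature > 0L & depth <= depthCutoff
    tab <- tabulate(tree$feature[use], nbins = length(nm))
    counts <- counts + tab
  }
  out <- data.table(feature = nm, count = counts)
  out[order(-count, feature)][count > 0L]
}
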