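#' Specification for a synthetic three-date fixture
#'
#' The generator emulates the statistical shape the discovery-and-re-ranking
#' method assumes: a concept inventory with 1-3 semantic types per concept, a
#' locally dense directed relation graph (topic clusters, so that typical
#' hidden pairs have several linking terms), promiscuous hub terms that the
#' outdegree filter and the linking-term stoplist must catch, a small
#' fraction of infrequent and negated relations for the per-triple filters,
#' snapshot growth over three dates, and a small planted subpopulation of
#' "interesting" new links whose feature signature — a single linking term
#' and a rare source/target semantic-type combination — differs from
#' background growth, which is drawn from high-linking-term candidates.
#'
#' @param nConcepts concept inventory size.
#' @param nSemtypes number of semantic types, of which \code{nRareTypes} are
#'   rare (used by the planted subpopulation and a handful of others).
#' @param semtypesPerConcept inclusive range of types per concept.
#' @param nRelationLabels number of positive relation labels (negated
#'   variants are prefixed \code{NEG_}).
#' @param clusterSize concepts per topic cluster.
#' @param clusterEdgeProb directed edge probability within a cluster.
#' @param lowCountFraction fraction of background triples given occurrence
#'   counts below 10 (disused relations, removed by the frequency filter).
#' @param negativeRelationFraction fraction of background triples given a
#'   negated predicate.
#' @param growthRate fraction of the triple count added as new direct links
#'   at each date step (background confirmations).
#' @param nPlantedInteresting number of planted interesting links (absent at
#'   date2, present at date3, discoverable candidates at date2).
#' @param nPeriphery number of rare-typed peripheral source/target concept
#'   pairs, each joined by a dedicated single-purpose bridge concept (its
#'   only linking term); the pool the planted links are drawn from.
#' @param hubCount,hubOutdegree hubs exceeding the outdegree filter.
#' @param stopHubCount,stopHubClusters promiscuous linking terms: each
#'   stop-hub receives edges from every member of \code{stopHubClusters}
#'   clusters and sends edges to every member of as many others, staying
#'   below the outdegree threshold while linking far more candidate pairs
#'   than any ordinary concept — the population the stoplist must catch.
#' @param nRareTypes number of rare semantic types.
#' @param seed RNG seed; two calls with the same spec are identical.
#' @return a validated list of class \code{SyntheticSpec}.
#' @export
syntheticSpec <- function(nConcepts = 2000L, nSemtypes = 20L,
                          semtypesPerConcept = c(1L, 3L),
                          nRelationLabels = 15L,
                          clusterSize = 20L, clusterEdgeProb = 0.6,
                          lowCountFraction = 0.1,
                          negativeRelationFraction = 0.05,
                          growthRate = 0.01,
                          nPlantedInteresting = 25L, nPeriphery = 120L,
                          hubCount = 3L, hubOutdegree = 250L,
                          stopHubCount = 2L, stopHubClusters = 2L,
                          nRareTypes = 2L, seed = 7L) {
  spec <- list(
    nConcepts = as.integer(nConcepts), nSemtypes = as.integer(nSemtypes),
    semtypesPerConcept = as.integer(semtypesPerConcept),
    nRelationLabels = as.integer(nRelationLabels),
    clusterSize = as.integer(clusterSize), clusterEdgeProb = clusterEdgeProb,
    lowCountFraction = lowCountFraction,
    negativeRelationFraction = negativeRelationFraction,
    growthRate = growthRate,
    nPlantedInteresting = as.integer(nPlantedInteresting),
    nPeriphery = as.integer(nPeriphery),
    hubCount = as.integer(hubCount), hubOutdegree = as.integer(hubOutdegree),
    stopHubCount = as.integer(stopHubCount),
    stopHubClusters = as.integer(stopHubClusters),
    nRareTypes = as.integer(nRareTypes), seed = as.integer(seed)
  )
  stopifnot(
    spec$nPeriphery >= spec$nPlantedInteresting,
    spec$nRareTypes >= 2L, spec$nSemtypes > spec$nRareTypes + 2L,
    spec$clusterEdgeProb > 0, spec$clusterEdgeProb < 1,
    spec$nConcepts > spec$hubCount + spec$stopHubCount + 3L * spec$nPeriphery +
      2L * spec$clusterSize
  )
  structure(spec, class = "SyntheticSpec")
}

#' Filter thresholds scaled to the synthetic fixture
#'
#' The full-release thresholds (outdegree 5000, linking-term count 10000)
#' are sized for millions of concepts; this scales them so that the
#' fixture's hubs exceed them while ordinary cluster members do not.  The
#' minimum relation frequency stays at 10.
#'
#' @param spec a [syntheticSpec()].
#' @return a [filterConfig()].
#' @export
fixtureFilterConfig <- function(spec = syntheticSpec()) {
  filterConfig(
    minRelFreq = 10L,
    outdegreeMax = as.integer(ceiling(spec$hubOutdegree * 0.6)),
    ltFreqMax = as.integer((spec$stopHubClusters * spec$clusterSize)^2 / 4)
  )
}

# sample background growth: new direct links drawn from HIGH-linking-term
# candidates (trivial knowledge has many links), never from `exclude`
sampleGrowth <- function(rawTriples, semtypes, dateLab, cfg, relLabels, nAdd,
                         exclude = NULL) {
  snap <- buildSnapshot(rawTriples, semtypes, dateLab)
  f <- applyFilters(snap, cfg)
  hk <- abcClosure(f$snapshot, f$stoplist)
  p <- candidatePairs(hk)
  if (!is.null(exclude)) p <- p[!exclude, on = c("source", "target")]
  p <- p[order(-nLinkingTerms, source, target)]
  poolSize <- max(nAdd, ceiling(0.3 * nrow(p)))
  pool <- head(p, poolSize)
  if (nAdd > nrow(pool)) stop("growth step infeasible: not enough candidates")
  pick <- pool[sample.int(nrow(pool), nAdd)]
  data.table(
    subject = pick$source,
    predicate = sample(relLabels, nAdd, replace = TRUE),
    object = pick$target,
    count = 10L + stats::rpois(nAdd, 20),
    negative = FALSE
  )
}

aggregateTriples <- function(tr) {
  out <- tr[, .(count = as.integer(sum(count))), by = .(subject, predicate, object, negative)]
  setcolorder(out, c("subject", "predicate", "object", "count", "negative"))
  setkey(out, subject, predicate, object)
  out[]
}

#' Generate a three-date synthetic fixture
#'
#' Builds the date1 graph (clusters + periphery + hubs), grows it to date2
#' and date3 by sampling background confirmations from high-linking-term
#' candidates, and plants \code{nPlantedInteresting} interesting links: pairs
#' chosen from the date2 closure whose linking-term count is strictly below
#' the background 10th percentile \emph{and} whose source/target
#' semantic-type combination occurs in less than 1\% of background
#' candidates.  Planted links are absent at date2, appear as direct triples
#' at date3, and are discoverable candidates of the filtered date2 snapshot;
#' both properties, and the anomalous-signature margins, are asserted before
#' returning.
#'
#' @param spec a [syntheticSpec()].
#' @return list with \code{snapshots} (raw \code{KnowledgeSnapshot}s for
#'   date1..3), \code{filterConfig} (fixture-scaled thresholds),
#'   \code{groundTruth} (planted pairs, per-step additions, hub and
#'   stop-hub ids, periphery pairs, linking-term counts, relation counts,
#'   per-date triple counts, signature margins) and \code{spec}.
#' @export
generateFixture <- function(spec = syntheticSpec()) {
  withSeed(spec$seed, generateFixtureImpl(spec))
}

generateFixtureImpl <- function(spec) {
  ids <- sprintf("C%04d", seq_len(spec$nConcepts))
  typeIds <- sprintf("T%02d", seq_len(spec$nSemtypes))
  rareTypes <- tail(typeIds, spec$nRareTypes)
  commonTypes <- setdiff(typeIds, rareTypes)
  relLabels <- sprintf("R%02d", seq_len(spec$nRelationLabels))

  k <- 0L
  takeIds <- function(n) { out <- ids[k + seq_len(n)]; k <<- k + n; out }
  hubIds <- takeIds(spec$hubCount)
  stopHubIds <- takeIds(spec$stopHubCount)
  periSrc <- takeIds(spec$nPeriphery)
  periTgt <- takeIds(spec$nPeriphery)
  periBridge <- takeIds(spec$nPeriphery)
  clusterable <- ids[(k + 1L):spec$nConcepts]
  nClusters <- length(clusterable) %/% spec$clusterSize
  clusters <- split(
    clusterable[seq_len(nClusters * spec$clusterSize)],
    rep(seq_len(nClusters), each = spec$clusterSize)
  )
  clusterMembers <- unlist(clusters, use.names = FALSE)

  # semantic types: every cluster member carries its cluster's dominant type
  # (topic clusters are semantically coherent), plus 0-2 Zipf-weighted extra
  # common types; so ordinary in-cluster pairs always realise a frequent
  # source/target type pairing
  zipf <- (1 / seq_along(commonTypes)); zipf <- zipf / sum(zipf)
  nTypesOf <- sample(seq(spec$semtypesPerConcept[1], spec$semtypesPerConcept[2]),
                     spec$nConcepts, replace = TRUE)
  semtypes <- lapply(nTypesOf, function(m)
    sample(commonTypes, m, prob = zipf, replace = FALSE))
  names(semtypes) <- ids
  clusterType <- commonTypes[((seq_len(nClusters) - 1L) %% length(commonTypes)) + 1L]
  for (ci in seq_len(nClusters)) {
    mem <- clusters[[ci]]
    semtypes[mem] <- lapply(semtypes[mem], function(t)
      unique(c(clusterType[ci], t))[seq_len(min(3L, length(t) + 1L))])
  }
  # periphery concepts (and their bridges) carry the rare types exclusively:
  # a semantic-type combination that never occurs in the background
  semtypes[periSrc] <- list(rareTypes)
  semtypes[periTgt] <- list(rareTypes)
  semtypes[periBridge] <- list(rareTypes)

  # date1 edges: dense directed topic clusters
  edgeList <- lapply(clusters, function(mem) {
    g <- CJ(subject = mem, object = mem)[subject != object]
    g[stats::runif(nrow(g)) < spec$clusterEdgeProb]
  })
  bg <- rbindlist(edgeList)
  nBg <- nrow(bg)
  bg[, predicate := sample(relLabels, nBg, replace = TRUE)]
  bg[, count := 10L + stats::rpois(nBg, 20)]
  low <- sample.int(nBg, round(spec$lowCountFraction * nBg))
  bg[low, count := sample(1:9, length(low), replace = TRUE)]
  neg <- sample.int(nBg, round(spec$negativeRelationFraction * nBg))
  bg[neg, predicate := paste0("NEG_", predicate)]
  bg[, negative := startsWith(predicate, "NEG_")]

  # periphery: rare-typed source/target pairs joined by a dedicated bridge,
  # so each pair is its endpoints' only candidate (a clean rare signature)
  peri <- data.table(
    subject = c(periSrc, periBridge),
    predicate = sample(relLabels, 2L * spec$nPeriphery, replace = TRUE),
    object = c(periBridge, periTgt),
    count = 10L + stats::rpois(2L * spec$nPeriphery, 20),
    negative = FALSE
  )

  # hubs: outdegree offenders and stoplist offenders
  hub <- rbindlist(lapply(hubIds, function(h) data.table(
    subject = h,
    predicate = sample(relLabels, spec$hubOutdegree, replace = TRUE),
    object = sample(clusterMembers, spec$hubOutdegree),
    count = 10L + stats::rpois(spec$hubOutdegree, 20),
    negative = FALSE
  )))
  # each stop-hub bridges whole clusters, so its endpoint candidates keep
  # many linking terms while it links ~ (k*clusterSize)^2 pairs as a B term
  stopHub <- rbindlist(lapply(seq_along(stopHubIds), function(si) {
    h <- stopHubIds[si]
    pick <- sample(nClusters, 2L * spec$stopHubClusters)
    inMem <- unlist(clusters[pick[seq_len(spec$stopHubClusters)]], use.names = FALSE)
    outMem <- unlist(clusters[pick[-seq_len(spec$stopHubClusters)]], use.names = FALSE)
    rbind(
      data.table(subject = inMem,
                 predicate = sample(relLabels, length(inMem), replace = TRUE),
                 object = h,
                 count = 10L + stats::rpois(length(inMem), 20),
                 negative = FALSE),
      data.table(subject = h,
                 predicate = sample(relLabels, length(outMem), replace = TRUE),
                 object = outMem,
                 count = 10L + stats::rpois(length(outMem), 20),
                 negative = FALSE)
    )
  }))

  triples1 <- aggregateTriples(rbind(bg, peri, hub, stopHub))
  cfg <- fixtureFilterConfig(spec)

  # grow to date2
  nAdd2 <- round(spec$growthRate * nrow(triples1))
  add2 <- sampleGrowth(triples1, semtypes, "date1", cfg, relLabels, nAdd2)
  triples2 <- aggregateTriples(rbind(triples1, add2))

  # choose planted interesting links from the date2 closure
  snap2f <- applyFilters(buildSnapshot(triples2, semtypes, "date2"), cfg)
  hk2 <- abcClosure(snap2f$snapshot, snap2f$stoplist)
  p2 <- candidatePairs(hk2)
  # a pair has a rare type combination when EVERY (source type, target type)
  # pairing it realises occurs in < 1% of background candidates
  p2[, row := .I]
  stLong <- data.table(id = rep(names(semtypes), lengths(semtypes)),
                       type = unlist(semtypes, use.names = FALSE))
  at <- merge(p2[, .(row, id = source)], stLong, by = "id", allow.cartesian = TRUE)
  ct <- merge(p2[, .(row, id = target)], stLong, by = "id", allow.cartesian = TRUE)
  tp <- merge(at[, .(row, ta = type)], ct[, .(row, tc = type)],
              by = "row", allow.cartesian = TRUE)
  tp[, pairFreq := .N / nrow(p2), by = .(ta, tc)]
  p2[, comboFreq := tp[, max(pairFreq), keyby = row]$V1]
  q10 <- as.numeric(stats::quantile(p2$nLinkingTerms, 0.10, type = 1))
  eligible <- p2[nLinkingTerms < q10 & comboFreq < 0.01]
  if (nrow(eligible) < spec$nPlantedInteresting)
    stop(sprintf(
      "spec infeasible: only %d candidates have the anomalous signature (n < %g and combo freq < 1%%) but %d planted links were requested",
      nrow(eligible), q10, spec$nPlantedInteresting))
  planted <- eligible[sample.int(nrow(eligible), spec$nPlantedInteresting),
                      .(source, target)]
  setkey(planted, source, target)

  # grow to date3: background confirmations plus the planted links
  nAdd3 <- round(spec$growthRate * nrow(triples2))
  add3 <- sampleGrowth(triples2, semtypes, "date2", cfg, relLabels, nAdd3,
                       exclude = planted)
  plantedTriples <- data.table(
    subject = planted$source,
    predicate = sample(relLabels, nrow(planted), replace = TRUE),
    object = planted$target,
    count = 10L + stats::rpois(nrow(planted), 20),
    negative = FALSE
  )
  triples3 <- aggregateTriples(rbind(triples2, add3, plantedTriples))

  snapshots <- list(
    date1 = buildSnapshot(triples1, semtypes, "date1"),
    date2 = buildSnapshot(triples2, semtypes, "date2"),
    date3 = buildSnapshot(triples3, semtypes, "date3")
  )

  # ground-truth bookkeeping and generation-time assertions
  lw <- unique(linkWitnesses(abcClosure(snap2f$snapshot, character()))[, .(source, target, b)])
  ltCounts <- lw[, .N, by = b][order(-N, b)]
  plantedRows <- p2[planted, on = c("source", "target")]
  stopifnot(
    nrow(fsetdiff(knownPairs(snapshots$date1), knownPairs(snapshots$date2))) == 0L,
    nrow(fsetdiff(knownPairs(snapshots$date2), knownPairs(snapshots$date3))) == 0L,
    nrow(fintersect(planted, knownPairs(snap2f$snapshot))) == 0L,
    nrow(fintersect(planted, candidatePairs(hk2)[, .(source, target)])) == nrow(planted),
    all(plantedRows$nLinkingTerms < q10),
    all(plantedRows$comboFreq < 0.01)
  )

  groundTruth <- list(
    planted = planted,
    additionsDate2 = add2[, .(source = subject, target = object)],
    additionsDate3 = add3[, .(source = subject, target = object)],
    hubIds = hubIds, stopHubIds = stopHubIds,
    peripheryPairs = data.table(source = periSrc, target = periTgt),
    ltCounts = ltCounts,
    relationCounts = triples1[, .N, by = predicate][order(predicate)],
    tripleCounts = c(date1 = nrow(triples1), date2 = nrow(triples2),
                     date3 = nrow(triples3)),
    signature = list(
      backgroundN10thPercentile = q10,
      plantedMaxN = if (nrow(plantedRows)) max(plantedRows$nLinkingTerms) else NA_integer_,
      medianBackgroundN = stats::median(p2$nLinkingTerms),
      plantedMaxComboFreq = if (nrow(plantedRows)) max(plantedRows$comboFreq) else NA_real_,
      rareSignatureRate = nrow(eligible) / nrow(p2)
    ),
    rareTypes = rareTypes
  )
  list(snapshots = snapshots, filterConfig = cfg,
       groundTruth = groundTruth, spec = spec)
}

#' Write a fixture to disk in the package's file dialects
#'
#' Emits \code{relations_date1.rrf} .. \code{relations_date3.rrf}
#' (pipe-delimited subject|predicate|object|count), \code{semtypes.rrf},
#' \code{filter_config.json} and \code{ground_truth.json}.  The relation and
#' semantic-type files round-trip through [readRRFRelations()] /
#' [readSemTypes()] to identical snapshots.
#'
#' @param fixture result of [generateFixture()].
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeFixtureFiles <- function(fixture, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create fixture directory ", dir)
  for (d in names(fixture$snapshots))
    writeRRFRelations(fixture$snapshots[[d]], file.path(dir, sprintf("relations_%s.rrf", d)))
  allSt <- semTypes(fixture$snapshots$date3)
  writeSemTypes(allSt, file.path(dir, "semtypes.rrf"))
  jsonlite::write_json(fixture$filterConfig[c("minRelFreq", "outdegreeMax", "ltFreqMax")],
                       file.path(dir, "filter_config.json"), auto_unbox = TRUE)
  jsonlite::write_json(fixture$groundTruth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, dataframe = "rows", digits = NA)
  invisible(dir)
}

#' Read a fixture directory back into snapshots
#'
#' @param dir directory written by [writeFixtureFiles()].
#' @return list with \code{snapshots}, \code{filterConfig} and
#'   \code{groundTruth} (tables as data.tables).
#' @export
readFixtureFiles <- function(dir) {
  st <- readSemTypes(file.path(dir, "semtypes.rrf"))
  snaps <- lapply(c("date1", "date2", "date3"), function(d) {
    buildSnapshot(readRRFRelations(file.path(dir, sprintf("relations_%s.rrf", d))), st, d)
  })
  names(snaps) <- c("date1", "date2", "date3")
  cfgRaw <- jsonlite::read_json(file.path(dir, "filter_config.json"))
  gt <- jsonlite::fromJSON(file.path(dir, "ground_truth.json"))
  for (nm in c("planted", "additionsDate2", "additionsDate3", "peripheryPairs",
               "ltCounts", "relationCounts"))
    if (!is.null(gt[[nm]])) gt[[nm]] <- as.data.table(gt[[nm]])
  list(
    snapshots = snaps,
    filterConfig = filterConfig(minRelFreq = cfgRaw$minRelFreq,
                                outdegreeMax = cfgRaw$outdegreeMax,
                                ltFreqMax = cfgRaw$ltFreqMax),
    groundTruth = gt
  )
}
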