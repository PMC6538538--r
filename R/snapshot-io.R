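#' Read a pipe-delimited relation file (metathesaurus-style)
#'
#' Parses headerless pipe-delimited rows into relation triples.  Column
#' positions are configurable so that MRREL-like layouts with extra columns
#' can be consumed; duplicate (subject, predicate, object) rows have their
#' counts summed.  Malformed lines (too few columns, empty fields,
#' non-numeric counts) are skipped with a logged tally; if more than half of
#' the non-empty lines are malformed the file is rejected as being in the
#' wrong dialect.
#'
#' @param path file to read.
#' @param cols named integer vector giving 1-based column positions for
#'   \code{subject}, \code{predicate}, \code{object} and optionally
#'   \code{count} (lines without a count column count once each).
#' @param negativePrefix predicates starting with this prefix are flagged
#'   negative (negated predications, e.g. \code{NEG_TREATS}).
#' @return \code{data.table} with columns \code{subject}, \code{predicate},
#'   \code{object}, \code{count}, \code{negative}.
#' @examples
#' f <- tempfile()
#' writeLines(c("C1|may_treat|C2", "C1|may_treat|C2", "C2|isa|C3"), f)
#' readRRFRelations(f)
#' @export
readRRFRelations <- function(path,
                             cols = c(subject = 1L, predicate = 2L, object = 3L, count = 4L),
                             negativePrefix = "NEG") {
  if (!file.exists(path)) stop("relation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(emptyTriples())
  parts <- strsplit(lines, "|", fixed = TRUE)
  need <- max(cols[c("subject", "predicate", "object")])
  nf <- lengths(parts)
  hasCount <- !is.na(cols["count"])

  subj <- pred <- obj <- rep(NA_character_, length(lines))
  ok <- nf >= need
  subj[ok] <- vapply(parts[ok], `[[`, "", cols[["subject"]])
  pred[ok] <- vapply(parts[ok], `[[`, "", cols[["predicate"]])
  obj[ok]  <- vapply(parts[ok], `[[`, "", cols[["object"]])
  cnt <- rep(1L, length(lines))
  if (hasCount) {
    has <- ok & nf >= cols[["count"]]
    raw <- rep(NA_character_, length(lines))
    raw[has] <- vapply(parts[has], `[[`, "", cols[["count"]])
    suppressWarnings(val <- as.integer(raw))
    cnt[has & !is.na(val)] <- val[has & !is.na(val)]
    ok <- ok & !(has & is.na(val))   # count column present but unparsable
  }
  ok <- ok & nzchar(subj) & nzchar(pred) & nzchar(obj) & !is.na(subj) & cnt >= 0L
  nBad <- sum(!ok)
  if (nBad > 0L) lbdLog("%s: skipped %d malformed line(s) of %d", basename(path), nBad, length(lines))
  if (nBad > length(lines) / 2)
    stop(sprintf("more than half of the lines in %s are malformed (%d/%d); wrong dialect?",
                 path, nBad, length(lines)))
  tr <- data.table(subject = subj[ok], predicate = pred[ok], object = obj[ok], count = cnt[ok])
  tr <- tr[, .(count = sum(count)), by = .(subject, predicate, object)]
  tr[, negative := startsWith(predicate, negativePrefix)]
  setcolorder(tr, c("subject", "predicate", "object", "count", "negative"))
  setkey(tr, subject, predicate, object)
  tr[]
}

#' Read a predication table (SemMedDB-style)
#'
#' Consumes tab- or comma-delimited subject-predicate-object predication rows
#' with a header naming (at least) \code{subject_cui}, \code{predicate} and
#' \code{object_cui}.  Predicates starting with \code{negativePrefix} are
#' flagged negative so that the filtering stage can drop negated assertions
#' such as \code{NEG_TREATS}.
#'
#' @param path file to read.
#' @param negativePrefix prefix marking negated predicates (default "NEG").
#' @return as [readRRFRelations()].
#' @export
readPredications <- function(path, negativePrefix = "NEG") {
  if (!file.exists(path)) stop("predication file not found: ", path)
  dt <- tryCatch(
    fread(path, header = TRUE, colClasses = "character", showProgress = FALSE),
    error = function(e) stop("cannot parse predication table ", path, ": ", conditionMessage(e))
  )
  need <- c("subject_cui", "predicate", "object_cui")
  if (!all(need %in% names(dt)))
    stop("predication table must have columns ", paste(need, collapse = ", "))
  if (nrow(dt) == 0L) return(emptyTriples())
  tr <- dt[, .(subject = subject_cui, predicate = predicate, object = object_cui)]
  bad <- !nzchar(tr$subject) | !nzchar(tr$predicate) | !nzchar(tr$object)
  if (any(bad)) {
    lbdLog("%s: skipped %d malformed row(s)", basename(path), sum(bad))
    if (sum(bad) > nrow(tr) / 2)
      stop("more than half of the predication rows are malformed; wrong dialect?")
    tr <- tr[!bad]
  }
  tr <- tr[, .(count = .N), by = .(subject, predicate, object)]
  tr[, count := as.integer(count)]
  tr[, negative := startsWith(predicate, negativePrefix)]
  setkey(tr, subject, predicate, object)
  tr[]
}

#' Read a concept-to-semantic-type file (MRSTY-style)
#'
#' Pipe-delimited headerless rows of (concept id, semantic type); a concept
#' may appear on several rows and accumulates all its types.
#'
#' @param path file to read.
#' @param cols 1-based positions of the concept-id and type columns.
#' @return named list mapping concept id to a character vector of types.
#' @export
readSemTypes <- function(path, cols = c(id = 1L, type = 2L)) {
  if (!file.exists(path)) stop("semantic-type file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(structure(list(), names = character()))
  parts <- strsplit(lines, "|", fixed = TRUE)
  ok <- lengths(parts) >= max(cols)
  if (any(!ok)) lbdLog("%s: skipped %d malformed line(s)", basename(path), sum(!ok))
  id <- vapply(parts[ok], `[[`, "", cols[["id"]])
  ty <- vapply(parts[ok], `[[`, "", cols[["type"]])
  keep <- nzchar(id) & nzchar(ty)
  dt <- unique(data.table(id = id[keep], type = ty[keep]))
  setkey(dt, id, type)
  split(dt$type, dt$id)
}

#' Write a snapshot's triples in the pipe-delimited dialect
#'
#' Emits \code{subject|predicate|object|count} rows in lexicographic
#' (subject, predicate, object) order, so that the output is byte-stable and
#' round-trips through [readRRFRelations()] to an identical triple multiset.
#'
#' @param x a \code{KnowledgeSnapshot} or a triples \code{data.table}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRRFRelations <- function(x, path) {
  tr <- if (is(x, "KnowledgeSnapshot")) triples(x) else as.data.table(x)
  tr <- tr[order(subject, predicate, object)]
  writeLines(paste(tr$subject, tr$predicate, tr$object, tr$count, sep = "|"), path)
  invisible(path)
}

#' Write a semantic-type mapping in the pipe-delimited dialect
#'
#' @param semtypes named list as returned by [readSemTypes()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSemTypes <- function(semtypes, path) {
  ids <- rep(names(semtypes), lengths(semtypes))
  ty <- unlist(semtypes, use.names = FALSE)
  o <- order(ids, ty)
  writeLines(paste(ids[o], ty[o], sep = "|"), path)
  invisible(path)
}
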