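# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

lbdLog <- function(fmt, ...) message(sprintf(paste0("[lbdrank] ", fmt), ...))

# Resource errors get their own condition class so callers (and the CLI) can
# map them to a dedicated exit code instead of crashing on allocation.
lbdResourceError <- function(msg) {
  stop(structure(
    class = c("lbdResourceError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

emptyTriples <- function() {
  data.table(
    subject = character(), predicate = character(), object = character(),
    count = integer(), negative = logical()
  )
}

asPairTable <- function(x) {
  x <- as.data.table(x)[, c("source", "target")]
  unique(x)
}
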