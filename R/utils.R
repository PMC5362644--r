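# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream. If seed is NULL the code runs on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # initialize the stream so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# scalar checks used by constructors
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == trunc(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

as_day <- function(x, what = "date") {
  out <- tryCatch(as.Date(x), error = function(e) NA)
  if (anyNA(out) && !anyNA(x)) {
    stop(sprintf("cannot interpret %s as calendar day(s): %s",
                 what, paste(utils::head(x, 3L), collapse = ", ")),
         call. = FALSE)
  }
  out
}
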