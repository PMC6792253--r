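# seed plumbing: every stochastic component draws from a named substream of
# one master seed, so stages are independently reproducible

# derive a 32-bit substream seed from (master seed, stream name)
.substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}

# set the RNG locally, returning the previous state for .restore_seed
.set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# run expr under a substream seed without disturbing the caller's RNG state
.with_substream <- function(seed, stream, expr) {
  old <- .set_local_seed(.substream_seed(seed, stream))
  on.exit(.restore_seed(old))
  expr
}

# one structured log line per pipeline stage
.stage_log <- function(stage, ..., verbose = TRUE) {
  if (!verbose) return(invisible(NULL))
  kv <- list(...)
  msg <- paste(sprintf("%s=%s", names(kv), vapply(kv, format, "")),
               collapse = " ")
  message(sprintf("[%s] %s", stage, msg))
}

# data.table subsetting semantics inside the package
.datatable.aware <- TRUE
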