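# Named RNG sub-streams: every stochastic stage derives its own seed from the
# master seed and a stream name, so stages are replayable independently and
# ensembles are reproducible.

#' Derive a named sub-seed from a master seed
#'
#' Deterministic hash of `(master, name)` into a positive 31-bit integer.
#' @param master integer master seed.
#' @param name character stream name (e.g. `"sprout"`, `"collapse"`).
#' @return positive integer seed.
#' @export
derive_seed <- function(master, name) {
  v <- utf8ToInt(name)
  h <- as.double(master %% 2147483647L)
  for (x in v) h <- (h * 31 + x) %% 2147483647
  as.integer(h %% 2147483562 + 1)
}

#' Evaluate an expression under a named RNG stream
#'
#' Seeds the RNG from [derive_seed()] and restores the previous RNG state
#' afterwards.
#' @param master master seed; @param name stream name; @param expr expression.
#' @return value of `expr`.
#' @export
with_stream <- function(master, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(derive_seed(master, name))
  expr
}
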