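#' @keywords internal
"_PACKAGE"

# Named RNG substreams derived from one root seed. Each stochastic element
# (placement, lateral offsets, localization noise, detection misses, the
# mid-cell coin, shot noise, bootstrap) draws from its own substream so that
# toggling one stage never shifts the draws of another.

substream_seed <- function(root_seed, name) {
  stopifnot(is.character(name), length(name) == 1L)
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer((as.numeric(root_seed) %% 2147483647 + h) %% 2147483647)
}

# Evaluate `expr` under the substream RNG, restoring the caller's RNG state.
with_substream <- function(root_seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(root_seed, name))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
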