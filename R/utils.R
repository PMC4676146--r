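# Internal helpers shared across the pipeline.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All user-facing randomness in the package flows through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic per-variant uniform deviate from (seed, variant_index), so
# the keep/drop decision for a variant does not depend on how the stream is
# chunked. A small multiplicative hash keeps distinct variants on distinct
# RNG streams; everything stays below 2^31.
variant_uniform <- function(seed, variant_index) {
  s <- (as.double(seed) %% 65521) * 32749 + as.double(variant_index) * 2654435
  s <- s %% 2147483587
  with_seed(as.integer(s) + 1L, stats::runif(1L))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("popclust_format_error", "error")))
}

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("popclust_param_error", "error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("popclust_io_error", "error")))
}
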