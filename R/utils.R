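#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG state, restoring the caller's state afterwards.
# All user-facing randomness in the package goes through this so that a seed
# argument fully determines the output without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive k reproducible sub-seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(what, msg) {
  stop(sprintf("invalid %s: %s", what, msg), call. = FALSE)
}
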