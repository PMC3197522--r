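# Internal helpers shared across modules.

# Derive a reproducible substream seed from a root seed and a stream name.
# Keeps results independent across pipeline stages while everything flows
# from one root seed. Stays below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(root_seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(root_seed) * 48271 + h) %% 2147483647L)
}

# Evaluate expr with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_rsn <- function(...) stop(..., call. = FALSE)

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop_rsn(msg)
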