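# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. A NULL seed leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seeds for pipeline stages; kept below 2^31 - 1.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 9973) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce a matrix-like object, keeping dimnames, and check numeric.
as_numeric_matrix <- function(x, what = "input") {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop(what, " must be numeric", call. = FALSE)
  m
}
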