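# Internal helpers: seeded evaluation and seed-stream derivation.
# All user-facing randomness flows through with_seed() so that the caller's
# RNG state is never disturbed and identical seeds give identical output.

with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-stream seed, kept strictly below 2^31 so it is always a
# valid R integer seed.
derive_seed <- function(seed, offset) {
  s <- (abs(as.numeric(seed)) %% 2147483629) + 1
  o <- abs(as.numeric(offset)) %% 2147483629
  as.integer((s * 48271 + o * 9973 + 12345) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_binary01 <- function(x) {
  is.numeric(x) && all(x %in% c(0, 1))
}

stop_thetapet <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "thetapet_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
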