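# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG state without disturbing the caller's
# stream. All generators route their randomness through this, which is what
# makes them pure functions of (parameters, seed).
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  env <- globalenv()
  hadSeed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed (kept within 32-bit integer range).
subSeed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483647)
}

stopifnotFinite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(what, " must be finite numeric", call. = FALSE)
  invisible(x)
}

clip01 <- function(x) {
  y <- pmin(1, pmax(0, x))
  dim(y) <- dim(x)
  y
}
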