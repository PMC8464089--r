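# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package funnel through this helper so
# that every public function is a pure function of (arguments, seed).
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic derived seed, kept inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  parts <- c(as.integer(seed), as.integer(c(...)))
  s <- 0
  for (p in parts) s <- (s * 69069 + p + 1) %% 2147483647
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
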