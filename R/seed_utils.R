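# Deterministic seeding helpers. Generators are pure functions of
# (parameters, seed): the global RNG state is saved and restored around every
# seeded draw, and a top-level seed fans out to per-generator child seeds by
# stable hashing of the generator name, so adding a generator never perturbs
# the others.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded generators never disturb the
#' caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stable child seed from a parent seed and a name
#'
#' Polynomial string hash combined with the parent seed, reduced modulo
#' 2^31 - 1 so the result is always a valid 32-bit integer seed.
#'
#' @param seed Parent integer seed.
#' @param name Generator name.
#' @return Integer child seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, name) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 131 + code) %% m
  as.integer((((as.numeric(seed) %% m) * 48271) + h) %% (m - 1) + 1)
}
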