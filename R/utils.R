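# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL means "use the current stream" (callers composing a larger
# seeded computation pass NULL so all randomness flows from one seed).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# index of the grid element closest to `target`
nearest_index <- function(grid, target) which.min(abs(grid - target))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
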