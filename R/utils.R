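# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Every randomized operation in the package
# routes its draws through this, so independent output tables come from
# independent streams and regenerating one table does not perturb the others.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Deterministic child seed for a named sub-stream of a master seed.
# Kept below 2^31 - 1 (R integers are 32-bit).
child_seed <- function(seed, stream) {
  streams <- c(
    map = 11L, truth = 23L, probes = 37L, expression = 47L,
    tracks = 59L, genes = 67L, dmr_select = 79L, dhs = 89L,
    states = 97L, replication = 101L, massarray = 107L
  )
  off <- streams[[stream]]
  as.integer((as.double(seed) * 7919 + off) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

msg <- function(...) message("[helpdmr] ", sprintf(...))

stopf <- function(...) stop(sprintf(...), call. = FALSE)
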