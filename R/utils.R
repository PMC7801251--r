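# Internal helpers.

# Run `expr` under a given RNG seed without disturbing the caller's RNG state.
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

frobenius <- function(m) sqrt(sum(m * m))

# Canonical unordered edge key "u|v" with u < v lexicographically.
edge_key <- function(u, v) {
  a <- pmin(u, v)
  b <- pmax(u, v)
  paste(a, b, sep = "|")
}
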