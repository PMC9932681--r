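# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# all permutations of 1..n as a list (n small; used for cluster-class mapping)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_permutations(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}
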