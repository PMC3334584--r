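# small shared utilities

# evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards; seed = NULL uses the current stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
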