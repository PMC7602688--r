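# Evaluate expr with a temporarily seeded RNG, restoring the caller's
# RNG state afterwards so library internals never disturb user streams.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Multinomial logit over 1..(m+1) with the last category as reference.
softmax_simplex <- function(a) {
  e <- exp(c(a, 0) - max(c(a, 0)))
  e / sum(e)
}

simplex_to_logratio <- function(p) {
  p <- pmax(p, 1e-12)
  log(p[-length(p)] / p[length(p)])
}
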