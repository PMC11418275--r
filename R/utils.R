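# misc internal helpers

# run code under a temporary RNG state, restoring the caller's stream
with_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# map tree: apply f to every leaf numeric array of a nested list
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- tree_map2(a[[nm]], b[[nm]], f)
    return(out)
  }
  f(a, b)
}

tree_scale <- function(a, s) {
  if (is.list(a)) return(lapply(a, tree_scale, s = s))
  a * s
}

# clamp to [0, 1] preserving array dims
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
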