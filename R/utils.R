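# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a stream seed from a master seed; stays below 2^31 - 1.
derive_seed <- function(seed, offset) {
  s <- (as.double(seed) %% 2147483647) * 7919 + as.double(offset) * 104729
  as.integer(s %% 2147483629 + 1)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0))
    stopf("`%s` must be finite and strictly positive", name)
  invisible(x)
}
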