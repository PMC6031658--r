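#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a local RNG seed without disturbing the caller's
# random state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Counter-based derivation of stage seeds from a master seed: every
# subject/condition/stage gets an independent, reproducible stream and all
# derived seeds stay below 2^31 - 1.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in idx) s <- (s * 69069 + as.double(k) * 104729 + 12345) %% 2147483647
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(...) message(sprintf(...))
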