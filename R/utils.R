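#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_efnet <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "efnet_error")))
}

# Draw a sub-seed for a named component from a master seed, staying within
# the 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, salt) {
  (as.integer(seed) + sum(utf8ToInt(salt)) * 10007L) %% 2147483587L
}
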