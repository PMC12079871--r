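# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never disturb
# the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed from a root seed and a stream index; keeps every
# resampling stream reproducible from one root seed while staying inside
# the 32-bit integer range.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 9973) %% 2147483647L)
}

clamp01 <- function(x, tol = 1e-12) {
  x[x < 0 & x > -tol] <- 0
  pmin(pmax(x, 0), 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_clpn <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "clpn_error")))
}
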