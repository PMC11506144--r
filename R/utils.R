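# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All exported stochastic functions
# funnel their randomness through this so a single integer seed makes any
# stage reproducible in isolation.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop("'seed' must be a single non-missing number", call. = FALSE)
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
    on.exit({
      if (had) assign(".Random.seed", old, envir = env)
      else if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed from a master seed and a vector of stage/replicate
# indices.  Multiplicative mixing modulo a Mersenne prime keeps results in
# 32-bit integer range and makes distinct index tuples map to distinct
# streams with overwhelming probability.
derive_seed <- function(master, ...) {
  idx <- c(...)
  m <- 2147483647 # 2^31 - 1
  s <- as.double(master) %% m
  for (k in idx) s <- (s * 48271 + as.double(k) + 1) %% m
  as.integer(s %% (m - 2) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_prob <- function(x, name, lo = 0, hi = 1,
                                  open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open_lo) x > lo else x >= lo) &&
    (if (open_hi) x < hi else x <= hi)
  if (!ok) stop(sprintf("'%s' must be a single value in %s%g, %g%s", name,
                        if (open_lo) "(" else "[", lo, hi,
                        if (open_hi) ")" else "]"), call. = FALSE)
  invisible(x)
}
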