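# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed afterwards so library calls never perturb user RNG.
# seed = NULL runs expr with the current RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, kept inside the
# 32-bit integer range. Deterministic, collision-free for index < 1e6 when
# base seeds are spaced by >= 1e6 (documented in the methods vignette).
derive_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) * 1000003 + as.numeric(index)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_degenerate <- function(msg) stop(msg, call. = FALSE)
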