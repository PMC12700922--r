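#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# route their randomness through this so that a `seed` argument never
# perturbs (and is never perturbed by) the global RNG stream.
with_seed <- function(seed, code) {
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
  force(code)
}

# Fold an angle in degrees into the acute range [0, 90].
fold_acute <- function(deg) {
  deg <- deg %% 180
  ifelse(deg > 90, 180 - deg, deg)
}

abort_ctpa <- function(msg, class) {
  stop(structure(
    class = c(class, "ctpaindices_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Error used throughout geometry when a required label is missing where the
# measurement needs it.
abort_structure_absent <- function(msg) abort_ctpa(msg, "structure_absent_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
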