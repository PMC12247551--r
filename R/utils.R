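# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded helpers do not
#' perturb an enclosing simulation stream. A `NULL` seed evaluates the code
#' against the current stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic child seed derivation; keeps results < 2^31 so they remain
# valid R integer seeds.
child_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + index) %% 2147483629)
}

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

fmt_p <- function(p) {
  ifelse(p < 1e-4, format(p, digits = 3, scientific = TRUE), signif(p, 4))
}
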