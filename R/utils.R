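# Small internal helpers shared across modules.

# Stefan-Boltzmann constant, W m-2 K-4
.sigma_sb <- 5.670374419e-8

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

c_to_k <- function(x) x + 273.15

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards
# so generators are reproducible without clobbering the global stream.
with_seed <- function(seed, code) {
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
    })
    set.seed(seed)
  }
  force(code)
}

stopifnot_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}
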