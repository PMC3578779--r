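# Internal numerical and RNG helpers.

# Scoped RNG: set a seed for a block of code and restore the caller's RNG
# state afterwards, so every stochastic function is deterministic given its
# seed argument and never perturbs the global stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(seed))
  list(
    restore = function() {
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }
  )
}

# Derive a child seed from a master seed; keeps results below 2^31 so they
# remain valid R integers.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 9973) %% 2147483629)
}

# log(mean(exp(x))) with overflow protection
log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
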