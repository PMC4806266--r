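# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards. Keeps nested seeded stages (e.g. a
# seeded cross-validation called from inside the firefly loop) from
# perturbing each other's streams.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Single numeric scalar check used across config validators.
is_scalar_num <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x)
}
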