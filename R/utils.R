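# RNG bookkeeping: simulation and experiment drivers are seeded
# explicitly but must not clobber the caller's RNG state.

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible()
}

#' Derive a reproducible substream seed
#'
#' All Monte-Carlo drivers take one master seed; independent random
#' streams (per grid point, per iteration) use
#' `(master_seed + 1000003 * stream) mod (2^31 - 1)`, which keeps every
#' derived seed a valid 32-bit integer. Stream counters are assigned
#' deterministically, so distributed or re-ordered runs reproduce the same
#' draws.
#'
#' @param master_seed integer master seed.
#' @param stream non-negative integer stream counter.
#' @return Integer seed.
#' @export
substream_seed <- function(master_seed, stream) {
  as.integer((as.numeric(master_seed) + 1000003 * as.numeric(stream)) %%
               2147483647)
}

# evaluate expr under a given seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}

# transfer inside Monte-Carlo drivers: test subjects are drawn from the
# same pool as the training group, so benign covariate-range
# extrapolation warnings are muffled (any other warning propagates)
quiet_transfer <- function(model, data) {
  withCallingHandlers(
    apply_transfer(model, data),
    tcombat_extrapolation_warning = function(w)
      invokeRestart("muffleWarning"))
}
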