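# RNG bookkeeping: functions that take a `seed` argument must not disturb
# the caller's RNG stream.
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
  invisible(NULL)
}

with_seed <- function(seed, code) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  force(code)
}

# Accepts a mapk_posterior, a matrix of draws, or a single parameter vector
# and returns an N x 12 matrix with canonical column names.
as_draws_matrix <- function(samples) {
  if (inherits(samples, "mapk_posterior")) return(samples$draws)
  if (inherits(samples, "mapk_params"))
    samples <- matrix(unclass(samples), nrow = 1,
                      dimnames = list(NULL, PARAM_NAMES))
  samples <- as.matrix(samples)
  if (ncol(samples) != 12L)
    stop("draws must have 12 columns (one per model parameter)")
  colnames(samples) <- PARAM_NAMES
  samples
}
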