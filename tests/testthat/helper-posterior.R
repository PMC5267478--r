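# Shared synthetic-calibration objects for the slower end-to-end tests.
# Computed once per test run and cached; every consumer sees the same
# seeded dataset and chains.
.mapkqb_cache <- new.env(parent = emptyenv())

calibration_dataset <- function() {
  if (is.null(.mapkqb_cache$data))
    .mapkqb_cache$data <- generate_dataset(design_spec(seed = 11))
  .mapkqb_cache$data
}

# three 2e4-step chains initialized near (but not at) the ground truth
recovery_posteriors <- function() {
  if (is.null(.mapkqb_cache$posts)) {
    data <- calibration_dataset()
    truth <- mapk_fixture("quasi_bistable")
    .mapkqb_cache$posts <- lapply(1:3, function(sd)
      mcmc_sample(data, n_steps = 2e4, seed = sd,
                  init = mapkqb:::jitter_params(truth, sd), n_keep = 500))
  }
  .mapkqb_cache$posts
}

# per-draw trajectory classification of the first chain
posterior_classification <- function() {
  if (is.null(.mapkqb_cache$pc))
    .mapkqb_cache$pc <- population_classify(recovery_posteriors()[[1]])
  .mapkqb_cache$pc
}

# per-draw steady-state classification at rest of the first chain
posterior_cba_bistable <- function() {
  if (is.null(.mapkqb_cache$cba)) {
    draws <- recovery_posteriors()[[1]]$draws
    .mapkqb_cache$cba <- vapply(seq_len(nrow(draws)), function(i)
      find_steady_states(mapk_params(draws[i, ]), 0,
                         cond_ngf())$classification == "bistable",
      logical(1))
  }
  .mapkqb_cache$cba
}
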