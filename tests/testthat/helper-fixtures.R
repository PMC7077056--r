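# The planted-module study fixture at its committed default parameters
# (300 lncRNAs, module of 15, nine networks, seed 42), generated once per
# test run and shared across files.
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_collection(sim_params())
    cache
  }
})

# A small fast variant for structural tests.
tiny_sim <- function(seed = 11) {
  simulate_collection(sim_params(
    n_lnc = 60L, n_mrna = 30L, n_mirna = 20L, n_protein = 15L, n_tf = 10L,
    module_size = 6L, rng_seed = seed
  ))
}

# Minimal LOOCV record tibble wrapping raw positive scores, for ROC tests.
cv_records <- function(scores) {
  tibble::new_tibble(tibble::tibble(
    held_out = paste0("g", seq_along(scores)), score = scores,
    rank = NA_real_, rank_among = NA_integer_, unrankable = FALSE
  ), class = "lnc_loocv")
}

# Random but valid fusion profiles for property tests.
random_profiles <- function(n, N, seed) {
  set.seed(seed)
  list(
    r = matrix(stats::runif(n * N, .Machine$double.eps, 1), n, N),
    t = sample(seq_len(N), n, replace = TRUE) / N,
    bs = stats::runif(n),
    ds = stats::runif(n)
  )
}
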