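# Memoised expensive fixtures shared across test files. Everything here is
# deterministic, so caching cannot couple tests.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

default_ss <- function() cached("ss", steady_state(model_params()))

kcc2_run <- function() {
  cached("kcc2", kcc2_block_experiment(washback = TRUE))
}

anion_run <- function() cached("anion", impermeant_anion_experiment())

# trajectory row closest to a given time
traj_at <- function(sim, t) {
  tr <- sim$trajectory
  tr[which.min(abs(tr$t - t)), ]
}
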