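# shared fixtures: small configs and datasets built in code

small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(
    n_generators = 2L, n_committee = 2L, n_oracles = 1L, input_dim = 2L,
    uncertainty_threshold = 0.1, patience = 2L,
    training_buffer_threshold = 8L, weight_sync_period = 5L,
    max_steps = 50L, seed = 11L, temperature = 10, friction = 1,
    oracle_cost = 2, train_cost = 1, epochs_per_flush = 10L,
    sampler = list(type = "uniform", lower = c(-1.5, -0.2),
                   upper = c(1.2, 2.0))
  )
  defaults[names(args)] <- args
  do.call(workflow_config, defaults)
}

# labeled samples on a tiny quadratic bowl, deterministic
bowl_dataset <- function(n, seed = 1L, d = 2L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    x <- stats::rnorm(d)
    list(coords = x, energy = sum(x^2), forces = -2 * x,
         sample_id = i, provenance = "bowl")
  })
}

# scripted trajectory for patience tests
fresh_traj <- function(patience_seed = 3L) {
  params <- integrator_params(dt = 0.01)
  propose_initial(0L, list(reference = c(0, 0), sigma = 0.1), params,
                  qbcflow:::rng_stream_new(patience_seed))
}

# count restarts produced by a scripted reliability sequence
restarts_for_sequence <- function(reliab, patience) {
  st <- fresh_traj()
  restarts <- 0L
  for (r in reliab) {
    out <- react_to_reliability(st, r, patience)
    st <- out$state
    if (out$action == "restart") {
      restarts <- restarts + 1L
      st <- restart_trajectory(st, list(reference = c(0, 0), sigma = 0.1),
                               integrator_params(dt = 0.01))
    }
  }
  restarts
}

ledger_cfg <- function(seed) {
  small_cfg(max_steps = 500L, seed = seed, training_buffer_threshold = 16L,
            epochs_per_flush = 15L)
}

event_field <- function(events, kind, field) {
  keep <- Filter(function(e) e$kind == kind, events)
  vapply(keep, function(e) as.numeric(e[[field]]), numeric(1))
}

forwarded_ids <- function(events) {
  keep <- Filter(function(e) e$kind == "PREDICTION" && isTRUE(e$forwarded),
                 events)
  vapply(keep, function(e) as.numeric(e$sample_id), numeric(1))
}
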