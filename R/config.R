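#' Workflow configuration
#'
#' Builds and validates the configuration that drives an active-learning run:
#' how many kernel instances of each role exist, the query-by-committee
#' uncertainty threshold, the patience budget for exploring uncertain regions,
#' buffer/synchronisation periods, integrator parameters for the demo
#' molecular-dynamics generator, and the committee regressor hyperparameters.
#'
#' All quantities are in reduced units (energy, length, mass and Boltzmann
#' constant equal to 1 unless the oracle defines otherwise).
#'
#' @param n_generators Number of exploration (generator) processes, >= 1.
#' @param n_committee Committee size M (one trainer and one predictor per
#'   member), >= 1.
#' @param n_oracles Number of labeling processes; >= 1 when the oracle kernel
#'   is enabled, may be 0 otherwise.
#' @param input_dim Flattened coordinate dimension D (atom-major x,y,z).
#' @param uncertainty_threshold Committee energy standard deviation above which
#'   a configuration is deemed unreliable and forwarded for labeling
#'   (same units as the predicted energy). Non-negative.
#' @param patience Number of consecutive unreliable steps a trajectory may take
#'   before it is restarted. Non-negative integer.
#' @param training_buffer_threshold Labeled-sample count at which the training
#'   data buffer is flushed to all trainers, >= 1.
#' @param weight_sync_period Trainers export weights every this many epochs,
#'   >= 1.
#' @param early_stop_patience Epochs without validation-loss improvement before
#'   a trainer halts.
#' @param max_steps Per-generator step bound at which the run terminates.
#' @param enable_oracle,enable_training Kernel switches; disabling both turns
#'   the workflow into a pure prediction--generation (inference) loop.
#' @param reinitialize_on_new_data If `TRUE`, trainers re-draw their initial
#'   weights whenever a batch arrives; the default (`FALSE`) continues from the
#'   current weights, the recommended policy during active learning.
#' @param seed Integer run seed; every stream of randomness is derived from it.
#' @param dt Integrator time step (reduced time), > 0.
#' @param friction Langevin friction coefficient (1/time); 0 together with
#'   `temperature = 0` gives microcanonical (NVE) velocity-Verlet dynamics.
#' @param temperature Thermostat temperature in reduced units, >= 0.
#' @param mass Particle mass per degree of freedom, > 0.
#' @param sampler Initial-condition sampler: list with `reference` (numeric,
#'   length `input_dim`), `sigma` (Gaussian displacement width), and optional
#'   `lower`/`upper` domain bounds (trajectories leaving the box restart).
#' @param hidden_units Hidden-layer width of each committee member.
#' @param learning_rate Adam learning rate for the trainers.
#' @param w_energy,w_force Weights of the energy and force mean-squared-error
#'   terms in the training loss.
#' @param epochs_per_flush Training epochs scheduled per ingested batch.
#' @param val_fraction Deterministic validation fraction (split by hash of
#'   sample id).
#' @param bootstrap If `TRUE`, each trainer resamples every ingested batch with
#'   replacement (bagging); default diversity comes from initialisation only.
#' @param oracle_cost Virtual-time cost of one oracle label in the serial
#'   scheduler (emulates an expensive labeler).
#' @param train_cost Virtual-time cost of one training epoch in the serial
#'   scheduler.
#' @param label_budget Optional cap on total oracle labels; once reached no
#'   further samples are forwarded.
#' @param oracle_queue_cap Optional bound on the oracle input buffer: an
#'   unreliable sample is forwarded only while fewer than this many samples
#'   are pending or in flight. Paces label requests to labeling capacity so a
#'   finite budget is spent over the whole run instead of on the first few
#'   (uninformed) trajectory segments. `NULL` (default) leaves the FIFO
#'   unbounded.
#' @param termination Termination criterion: `list(type = "max_steps")`
#'   (default) or `list(type = "converged", window = w, max_unreliable_frac =
#'   f)` under which a generator signals shutdown once its trailing window of
#'   `w` predictions contains at most a fraction `f` of unreliable ones.
#' @param has_initial_data Set to `TRUE` when an initial labeled dataset will
#'   be supplied; allows `enable_training` without `enable_oracle`.
#'
#' @return A validated configuration object of class `"qbc_config"`.
#' @seealso [validate_config()], [read_config()], [run_workflow()]
#' @export
workflow_config <- function(n_generators = 2L,
                            n_committee = 4L,
                            n_oracles = 1L,
                            input_dim = 2L,
                            uncertainty_threshold = 2,
                            patience = 2L,
                            training_buffer_threshold = 16L,
                            weight_sync_period = 5L,
                            early_stop_patience = 25L,
                            max_steps = 500L,
                            enable_oracle = TRUE,
                            enable_training = TRUE,
                            reinitialize_on_new_data = FALSE,
                            seed = 1L,
                            dt = 0.005,
                            friction = 2,
                            temperature = 15,
                            mass = 1,
                            sampler = NULL,
                            hidden_units = 24L,
                            learning_rate = 0.02,
                            w_energy = 1,
                            w_force = 0.1,
                            epochs_per_flush = 30L,
                            val_fraction = 0.1,
                            bootstrap = FALSE,
                            oracle_cost = 5,
                            train_cost = 2,
                            label_budget = NULL,
                            oracle_queue_cap = NULL,
                            termination = list(type = "max_steps"),
                            has_initial_data = FALSE) {
  cfg <- list(
    n_generators = n_generators, n_committee = n_committee,
    n_oracles = n_oracles, input_dim = input_dim,
    uncertainty_threshold = uncertainty_threshold, patience = patience,
    training_buffer_threshold = training_buffer_threshold,
    weight_sync_period = weight_sync_period,
    early_stop_patience = early_stop_patience, max_steps = max_steps,
    enable_oracle = enable_oracle, enable_training = enable_training,
    reinitialize_on_new_data = reinitialize_on_new_data, seed = seed,
    dt = dt, friction = friction, temperature = temperature, mass = mass,
    sampler = sampler, hidden_units = hidden_units,
    learning_rate = learning_rate, w_energy = w_energy, w_force = w_force,
    epochs_per_flush = epochs_per_flush, val_fraction = val_fraction,
    bootstrap = bootstrap, oracle_cost = oracle_cost, train_cost = train_cost,
    label_budget = label_budget, oracle_queue_cap = oracle_queue_cap,
    termination = termination,
    has_initial_data = has_initial_data
  )
  validate_config(cfg)
}

#' Validate and normalise a workflow configuration
#'
#' Fills defaults, coerces counts to integers, and rejects inconsistent
#' configurations with an error naming the violated invariant.
#'
#' @param cfg A list of configuration fields (e.g. parsed from YAML) or a
#'   `"qbc_config"` object.
#' @return The normalised `"qbc_config"` object.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  known <- names(formals(workflow_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  defaults <- formals(workflow_config)
  for (nm in known) {
    if (is.null(cfg[[nm]]) && !nm %in% names(cfg)) {
      cfg[[nm]] <- eval(defaults[[nm]])
    }
  }

  int_fields <- c("n_generators", "n_committee", "n_oracles", "input_dim",
                  "patience", "training_buffer_threshold", "weight_sync_period",
                  "early_stop_patience", "max_steps", "seed", "hidden_units",
                  "epochs_per_flush")
  for (nm in int_fields) {
    v <- cfg[[nm]]
    if (length(v) != 1L || !is.numeric(v) || !is.finite(v) || v != round(v)) {
      stop("configuration field '", nm, "' must be a single integer")
    }
    cfg[[nm]] <- as.integer(v)
  }

  chk <- function(ok, msg) if (!ok) stop("invalid configuration: ", msg)
  chk(cfg$n_generators >= 1L, "n_generators must be >= 1")
  chk(cfg$n_committee >= 1L, "n_committee must be >= 1")
  chk(cfg$input_dim >= 1L, "input_dim must be >= 1")
  chk(cfg$uncertainty_threshold >= 0, "uncertainty_threshold must be >= 0")
  chk(cfg$patience >= 0L, "patience must be >= 0")
  chk(cfg$training_buffer_threshold >= 1L,
      "training_buffer_threshold must be >= 1")
  chk(cfg$weight_sync_period >= 1L, "weight_sync_period must be >= 1")
  chk(cfg$early_stop_patience >= 1L, "early_stop_patience must be >= 1")
  chk(cfg$max_steps >= 1L, "max_steps must be >= 1")
  chk(cfg$dt > 0, "dt must be > 0")
  chk(cfg$friction >= 0, "friction must be >= 0")
  chk(cfg$temperature >= 0, "temperature must be >= 0")
  chk(cfg$mass > 0, "mass must be > 0")
  chk(cfg$val_fraction >= 0 && cfg$val_fraction < 1,
      "val_fraction must be in [0, 1)")
  chk(cfg$oracle_cost >= 0 && cfg$train_cost >= 0,
      "virtual costs must be >= 0")
  if (cfg$enable_oracle) {
    chk(cfg$n_oracles >= 1L, "n_oracles must be >= 1 when the oracle kernel is enabled")
  } else {
    chk(cfg$n_oracles >= 0L, "n_oracles must be >= 0")
  }
  if (cfg$enable_training && !cfg$enable_oracle && !isTRUE(cfg$has_initial_data)) {
    stop("invalid configuration: enable_training requires enable_oracle ",
         "(no source of labels) unless an initial dataset is supplied")
  }
  if (!is.null(cfg$label_budget)) {
    chk(is.numeric(cfg$label_budget) && cfg$label_budget >= 1,
        "label_budget must be >= 1 when given")
    cfg$label_budget <- as.integer(cfg$label_budget)
  }

  if (!is.null(cfg$oracle_queue_cap)) {
    chk(is.numeric(cfg$oracle_queue_cap) && cfg$oracle_queue_cap >= 1,
        "oracle_queue_cap must be >= 1 when given")
    cfg$oracle_queue_cap <- as.integer(cfg$oracle_queue_cap)
  }

  if (is.null(cfg$sampler)) {
    cfg$sampler <- list(type = "gaussian",
                        reference = numeric(cfg$input_dim), sigma = 0.5,
                        lower = NULL, upper = NULL)
  }
  s <- cfg$sampler
  if (is.null(s$type)) s$type <- "gaussian"
  chk(s$type %in% c("gaussian", "uniform"),
      "sampler$type must be 'gaussian' or 'uniform'")
  if (s$type == "gaussian") {
    chk(!is.null(s$reference) && !is.null(s$sigma),
        "gaussian sampler must supply 'reference' and 'sigma'")
    chk(length(s$reference) == cfg$input_dim,
        "sampler$reference length must equal input_dim")
    chk(s$sigma >= 0, "sampler$sigma must be >= 0")
  } else {
    chk(!is.null(s$lower) && !is.null(s$upper),
        "uniform sampler must supply 'lower' and 'upper'")
  }
  if (!is.null(s$lower)) chk(length(s$lower) == cfg$input_dim,
                             "sampler$lower length must equal input_dim")
  if (!is.null(s$upper)) chk(length(s$upper) == cfg$input_dim,
                             "sampler$upper length must equal input_dim")
  cfg$sampler <- s

  t <- cfg$termination
  chk(is.list(t) && t$type %in% c("max_steps", "converged"),
      "termination$type must be 'max_steps' or 'converged'")
  if (t$type == "converged") {
    chk(!is.null(t$window) && t$window >= 1,
        "converged termination needs a window >= 1")
    if (is.null(t$max_unreliable_frac)) t$max_unreliable_frac <- 0
    chk(t$max_unreliable_frac >= 0 && t$max_unreliable_frac < 1,
        "max_unreliable_frac must be in [0, 1)")
    t$window <- as.integer(t$window)
    cfg$termination <- t
  }

  structure(cfg, class = "qbc_config")
}

#' @export
print.qbc_config <- function(x, ...) {
  cat("<qbc_config>\n")
  cat(sprintf("  kernels: %d generator(s), committee M=%d, %d oracle(s)%s%s\n",
              x$n_generators, x$n_committee, x$n_oracles,
              if (x$enable_oracle) "" else " [oracle disabled]",
              if (x$enable_training) "" else " [training disabled]"))
  cat(sprintf("  input_dim=%d  uncertainty_threshold=%g  patience=%d\n",
              x$input_dim, x$uncertainty_threshold, x$patience))
  cat(sprintf("  buffer_threshold=%d  sync_period=%d  max_steps=%d  seed=%d\n",
              x$training_buffer_threshold, x$weight_sync_period,
              x$max_steps, x$seed))
  cat(sprintf("  integrator: dt=%g friction=%g temperature=%g mass=%g\n",
              x$dt, x$friction, x$temperature, x$mass))
  invisible(x)
}

#' Read / write a workflow configuration file
#'
#' The canonical on-disk dialect is YAML with exactly the keys of
#' [workflow_config()]; unknown keys are errors, not warnings, so that typos
#' cannot silently fall back to defaults.
#'
#' @param path File path.
#' @return `read_config()` returns a validated `"qbc_config"`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sampler)) {
    raw$sampler <- lapply(raw$sampler, function(v) if (is.list(v)) unlist(v) else v)
  }
  validate_config(raw)
}

#' @param cfg A `"qbc_config"` object.
#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  out <- unclass(cfg)
  yaml::write_yaml(out, path)
  invisible(path)
}
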