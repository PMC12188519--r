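#' @title Generator kernel: surrogate-driven exploration trajectories
#' @description Each generator runs an independent molecular-dynamics
#'   trajectory propagated on the committee-mean forces. The integrator is a
#'   velocity-Verlet/Langevin splitting in which the closing half-kick is
#'   applied when the force at the new position arrives with the next
#'   prediction; with zero friction and temperature it reduces exactly to
#'   microcanonical leapfrog/velocity-Verlet dynamics. Each generator owns a
#'   private RNG stream, so trajectories are reproducible regardless of
#'   scheduling order, and applies patience-based restart logic to
#'   unreliable predictions.
#' @name generator
NULL

# --- private RNG streams -------------------------------------------------
# Each generator stores a full .Random.seed vector; draws restore it, sample,
# and save it back, so streams are independent of global RNG use and of the
# order in which generators are serviced.

rng_stream_new <- function(seed) {
  old <- get0(".Random.seed", envir = .GlobalEnv)
  set.seed(seed)
  s <- get(".Random.seed", envir = .GlobalEnv)
  if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  s
}

with_stream <- function(stream, fn) {
  old <- get0(".Random.seed", envir = .GlobalEnv)
  assign(".Random.seed", stream, envir = .GlobalEnv)
  value <- fn()
  stream <- get(".Random.seed", envir = .GlobalEnv)
  if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  list(value = value, stream = stream)
}

#' Integrator parameters
#'
#' @param dt Time step (reduced time), > 0.
#' @param friction Langevin friction coefficient; 0 disables the thermostat.
#' @param temperature Thermostat temperature (reduced); 0 with zero friction
#'   gives NVE dynamics.
#' @param mass Mass per degree of freedom, > 0.
#' @return A `"qbc_integrator"` list.
#' @export
integrator_params <- function(dt = 0.005, friction = 0, temperature = 0,
                              mass = 1) {
  stopifnot(dt > 0, friction >= 0, temperature >= 0, mass > 0)
  structure(list(dt = dt, friction = friction, temperature = temperature,
                 mass = mass),
            class = "qbc_integrator")
}

#' Draw a fresh trajectory state
#'
#' Positions are either the sampler reference plus Gaussian displacement of
#' width `sigma` (`type = "gaussian"`, the default) or uniform over the
#' `lower`/`upper` box (`type = "uniform"`, for global surface coverage);
#' velocities are Maxwell-Boltzmann at the integrator temperature (exactly
#' zero when `temperature = 0`). Reproducible: the same stream state yields
#' the same trajectory state.
#'
#' @param generator_id Generator index (0-based).
#' @param sampler List with `type` (`"gaussian"` or `"uniform"`),
#'   `reference`/`sigma` or box bounds, and optional `lower`/`upper` domain
#'   bounds (trajectories leaving the box restart).
#' @param params [integrator_params()].
#' @param stream A private RNG stream (from the run seed); pass the stream
#'   stored in the previous state to continue it.
#' @return A `"qbc_trajectory"` state: positions, velocities, `step`,
#'   `patience_counter`, `status`, `rng_state`, reliability window.
#' @export
propose_initial <- function(generator_id, sampler, params, stream) {
  uniform <- identical(sampler$type, "uniform")
  D <- if (uniform) length(sampler$lower) else length(sampler$reference)
  out <- with_stream(stream, function() {
    x <- if (uniform) {
      stats::runif(D, sampler$lower, sampler$upper)
    } else if (sampler$sigma > 0) {
      sampler$reference + stats::rnorm(D, sd = sampler$sigma)
    } else {
      sampler$reference
    }
    v <- if (params$temperature > 0) {
      stats::rnorm(D, sd = sqrt(params$temperature / params$mass))
    } else numeric(D)
    list(x = x, v = v)
  })
  structure(list(generator_id = as.integer(generator_id),
                 positions = out$value$x,
                 velocities = out$value$v,
                 step = 0L,
                 patience_counter = 0L,
                 restarts = 0L,
                 pending_kick = FALSE,
                 status = "running",
                 rng_state = out$stream,
                 window = logical(0)),
            class = "qbc_trajectory")
}

#' One integration step on supplied (committee-mean) forces
#'
#' Splitting per call, given the force F at the current position: close the
#' previous step's half-kick with F, half-kick with F, half-drift, Langevin
#' O-step (exact Ornstein-Uhlenbeck update when friction > 0), half-drift.
#' The closing half-kick with the force at the new position is deferred to
#' the next call, which is when that force becomes available from the
#' prediction kernel. Synchronised velocities for energy bookkeeping are
#' available via [sync_velocities()].
#'
#' If the step produces a non-finite state, or the position leaves the
#' sampler box, the trajectory status becomes `"restarting"`.
#'
#' @param state A `"qbc_trajectory"` with status `"running"`.
#' @param forces Force vector at `state$positions` (same length).
#' @param params [integrator_params()].
#' @param sampler Sampler spec carrying the optional domain box.
#' @return The advanced state (step counter incremented).
#' @export
md_step <- function(state, forces, params, sampler = NULL) {
  stopifnot(inherits(state, "qbc_trajectory"),
            state$status == "running",
            length(forces) == length(state$positions))
  dt <- params$dt; m <- params$mass
  v <- state$velocities
  if (state$pending_kick) v <- v + 0.5 * dt * forces / m  # close previous step
  v <- v + 0.5 * dt * forces / m                          # opening half-kick
  x <- state$positions + 0.5 * dt * v
  if (params$friction > 0) {
    c1 <- exp(-params$friction * dt)
    c2 <- sqrt((1 - c1^2) * params$temperature / m)
    out <- with_stream(state$rng_state, function() stats::rnorm(length(v)))
    v <- c1 * v + c2 * out$value
    state$rng_state <- out$stream
  }
  x <- x + 0.5 * dt * v
  state$positions <- x
  state$velocities <- v
  state$pending_kick <- TRUE
  state$step <- state$step + 1L
  bad <- !all(is.finite(x)) || !all(is.finite(v))
  if (!bad && !is.null(sampler)) {
    if (!is.null(sampler$lower) && any(x < sampler$lower)) bad <- TRUE
    if (!is.null(sampler$upper) && any(x > sampler$upper)) bad <- TRUE
  }
  if (bad) state$status <- "restarting"
  state
}

#' Synchronised velocities (for kinetic energy at the current position)
#'
#' Completes the pending half-kick with the supplied current-position force
#' without mutating the trajectory, giving velocities synchronous with the
#' positions.
#'
#' @param state A `"qbc_trajectory"`.
#' @param forces Force at `state$positions`.
#' @param params [integrator_params()].
#' @return Numeric velocity vector.
#' @export
sync_velocities <- function(state, forces, params) {
  v <- state$velocities
  if (state$pending_kick) v <- v + 0.5 * params$dt * forces / params$mass
  v
}

#' React to the controller's reliability verdict
#'
#' Memoryless patience rule: a reliable prediction resets the counter and the
#' trajectory propagates; an unreliable one increments the counter, and the
#' trajectory still propagates (into the uncertain region) while the counter
#' stays within the patience budget, restarting on the step after the budget
#' is exhausted.
#'
#' @param state A `"qbc_trajectory"`.
#' @param reliable Controller verdict for the state's latest sample.
#' @param patience Non-negative patience budget.
#' @return List with `action` (`"propagate"`, `"count_and_propagate"`, or
#'   `"restart"`) and the updated `state`.
#' @export
react_to_reliability <- function(state, reliable, patience) {
  stopifnot(patience >= 0)
  state$window <- c(state$window, !reliable)
  if (reliable) {
    state$patience_counter <- 0L
    return(list(action = "propagate", state = state))
  }
  state$patience_counter <- state$patience_counter + 1L
  if (state$patience_counter <= patience) {
    list(action = "count_and_propagate", state = state)
  } else {
    state$status <- "restarting"
    list(action = "restart", state = state)
  }
}

#' Restart a trajectory from the global initial sampler
#'
#' Continues the generator's private RNG stream; the step counter continues
#' (a restart does not reset exploration progress accounting) and the
#' patience counter is cleared. Pre-restart samples already forwarded for
#' labeling remain in flight.
#'
#' @param state A `"qbc_trajectory"` (any status).
#' @param sampler,params As in [propose_initial()].
#' @return The restarted `"qbc_trajectory"`.
#' @export
restart_trajectory <- function(state, sampler, params) {
  fresh <- propose_initial(state$generator_id, sampler, params,
                           state$rng_state)
  fresh$step <- state$step
  fresh$restarts <- state$restarts + 1L
  fresh$window <- state$window
  fresh
}

#' Check a generator's shutdown criterion
#'
#' Demo criteria: `max_steps` (total steps reached) or `converged` (the
#' trailing window of reliability verdicts is full and its unreliable
#' fraction is at or below the configured floor, i.e. the committee no longer
#' requests labels along this trajectory).
#'
#' @param state A `"qbc_trajectory"`.
#' @param criterion `list(type = "max_steps", max_steps = n)` or
#'   `list(type = "converged", window = w, max_unreliable_frac = f)`.
#' @return `TRUE` exactly when the criterion holds.
#' @export
check_termination <- function(state, criterion) {
  switch(criterion$type,
    max_steps = state$step >= criterion$max_steps,
    converged = {
      w <- criterion$window
      n <- length(state$window)
      if (n < w) return(FALSE)
      frac <- mean(utils::tail(state$window, w))
      frac <= criterion$max_unreliable_frac
    },
    stop("unknown termination criterion type '", criterion$type, "'")
  )
}

#' Microcanonical reference integration against an oracle
#'
#' Propagates NVE dynamics directly on an oracle's exact forces (bypassing
#' the committee) and records total energy per step with synchronised
#' velocities; the probe for integrator correctness.
#'
#' @param oracle A `"qbc_oracle"`.
#' @param x0,v0 Initial positions and velocities.
#' @param dt Time step.
#' @param n_steps Number of steps.
#' @param mass Mass per degree of freedom.
#' @return List with `positions` (final), `energies` (length `n_steps + 1`
#'   total energy trace), `max_rel_drift`.
#' @export
run_nve <- function(oracle, x0, v0, dt, n_steps, mass = 1) {
  params <- integrator_params(dt = dt, friction = 0, temperature = 0,
                              mass = mass)
  sampler <- list(reference = x0, sigma = 0)
  state <- propose_initial(0L, sampler, params, rng_stream_new(1L))
  state$velocities <- v0
  energy_at <- function(st) {
    f <- -oracle$gradient(st$positions)
    vs <- sync_velocities(st, f, params)
    oracle$energy(st$positions) + 0.5 * mass * sum(vs^2)
  }
  energies <- numeric(n_steps + 1L)
  energies[1L] <- energy_at(state)
  for (k in seq_len(n_steps)) {
    f <- -oracle$gradient(state$positions)
    state <- md_step(state, f, params)
    energies[k + 1L] <- energy_at(state)
  }
  e0 <- energies[1L]
  list(positions = state$positions, energies = energies,
       max_rel_drift = max(abs(energies - e0)) / abs(e0))
}
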