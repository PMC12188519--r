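test_that("initial states are reproducible and respect degenerate settings", {
  params <- integrator_params(dt = 0.01, temperature = 2)
  sam <- list(reference = c(1, -1), sigma = 0.3)
  s1 <- propose_initial(0L, sam, params, qbcflow:::rng_stream_new(5L))
  s2 <- propose_initial(0L, sam, params, qbcflow:::rng_stream_new(5L))
  expect_identical(s1, s2)

  # sigma = 0: positions equal the reference exactly
  s <- propose_initial(0L, list(reference = c(2, 3), sigma = 0), params,
                       qbcflow:::rng_stream_new(1L))
  expect_identical(s$positions, c(2, 3))

  # T = 0: zero initial velocities
  cold <- integrator_params(dt = 0.01, temperature = 0)
  s <- propose_initial(0L, sam, cold, qbcflow:::rng_stream_new(1L))
  expect_identical(s$velocities, c(0, 0))
})

test_that("zero forces at zero friction give straight-line motion", {
  params <- integrator_params(dt = 0.1, friction = 0, temperature = 0)
  st <- propose_initial(0L, list(reference = c(0, 0), sigma = 0), params,
                        qbcflow:::rng_stream_new(1L))
  st$velocities <- c(1, -2)
  for (k in 1:10) st <- md_step(st, c(0, 0), params)
  expect_equal(st$positions, c(1, -2) * 0.1 * 10, tolerance = 1e-12)
  expect_identical(st$step, 10L)
})

test_that("harmonic motion matches an independent high-accuracy integration", {
  # 1-D oscillator, dt = 0.01 over t = 100; bound pinned from a reference
  # solve at rtol 1e-12 (max deviation measured 4.1e-4, O(dt^2) phase error)
  params <- integrator_params(dt = 0.01, friction = 0, temperature = 0,
                              mass = 1)
  st <- propose_initial(0L, list(reference = 1, sigma = 0), params,
                        qbcflow:::rng_stream_new(1L))
  n <- 10000L
  xs <- numeric(n + 1L)
  xs[1] <- st$positions
  for (k in seq_len(n)) {
    st <- md_step(st, -st$positions, params)
    xs[k + 1L] <- st$positions
  }
  ref <- deSolve::ode(c(x = 1, v = 0), times = (0:n) * 0.01,
                      func = function(t, y, p) list(c(y[2], -y[1])),
                      rtol = 1e-12, atol = 1e-12)
  expect_lt(max(abs(xs - ref[, "x"])), 1e-3)
})

test_that("the thermostat equilibrates kinetic energy to T/2 per dof", {
  params <- integrator_params(dt = 0.05, friction = 1, temperature = 0.5,
                              mass = 1)
  st <- propose_initial(0L, list(reference = 0, sigma = 0), params,
                        qbcflow:::rng_stream_new(7L))
  ke <- 0
  n <- 100000L
  burn <- 5000L
  for (k in seq_len(n)) {
    f <- -st$positions
    if (k > burn) {
      vs <- sync_velocities(st, f, params)
      ke <- ke + 0.5 * vs^2
    }
    st <- md_step(st, f, params)
  }
  expect_equal(ke / (n - burn), 0.25, tolerance = 0.05)
})

test_that("NVE dynamics on exact dimer forces conserves total energy", {
  oracle <- oracle_lennard_jones()
  res <- run_nve(oracle, c(0, 0, 0, 1.5, 0, 0), rep(0, 6),
                 dt = 1e-3, n_steps = 10000L)
  expect_lt(res$max_rel_drift, 1e-4)
})

test_that("patience semantics: restart after p+1 consecutive unreliable steps", {
  # p = 0: first unreliable step restarts immediately
  expect_identical(restarts_for_sequence(c(FALSE), 0L), 1L)
  # p = 3: three unreliable then reliable resets the counter, no restart
  expect_identical(restarts_for_sequence(c(FALSE, FALSE, FALSE, TRUE), 3L), 0L)
  # p = 3: the fourth consecutive unreliable step restarts
  expect_identical(restarts_for_sequence(rep(FALSE, 4), 3L), 1L)
  # reliable steps reset: interleaving never reaches the budget
  expect_identical(
    restarts_for_sequence(rep(c(FALSE, FALSE, TRUE), 5), 3L), 0L)
})

test_that("counter resets on any reliable step and actions are reported", {
  st <- fresh_traj()
  out <- react_to_reliability(st, FALSE, 2L)
  expect_identical(out$action, "count_and_propagate")
  expect_identical(out$state$patience_counter, 1L)
  out <- react_to_reliability(out$state, TRUE, 2L)
  expect_identical(out$action, "propagate")
  expect_identical(out$state$patience_counter, 0L)
})

test_that("termination criteria fire exactly when they hold", {
  st <- fresh_traj()
  st$step <- 1000L
  expect_true(check_termination(st, list(type = "max_steps",
                                         max_steps = 1000L)))
  st$step <- 999L
  expect_false(check_termination(st, list(type = "max_steps",
                                          max_steps = 1000L)))
  # convergence: full window with no unreliable predictions signals
  st$window <- rep(FALSE, 50)
  expect_true(check_termination(st, list(type = "converged", window = 50L,
                                         max_unreliable_frac = 0)))
  st$window[25] <- TRUE
  expect_false(check_termination(st, list(type = "converged", window = 50L,
                                          max_unreliable_frac = 0)))
  # a partially filled window never signals
  st$window <- rep(FALSE, 10)
  expect_false(check_termination(st, list(type = "converged", window = 50L,
                                          max_unreliable_frac = 0)))
})

test_that("generators are independent of servicing order", {
  params <- integrator_params(dt = 0.01, friction = 1, temperature = 5)
  sam <- list(reference = c(0, 0), sigma = 0.2)
  run_in_order <- function(order) {
    states <- lapply(0:1, function(g) {
      propose_initial(g, sam, params,
                      qbcflow:::rng_stream_new(qbcflow:::derive_seed(3L, g)))
    })
    for (k in 1:50) {
      for (g in order) {
        states[[g]] <- md_step(states[[g]], -states[[g]]$positions, params)
      }
    }
    states
  }
  expect_identical(run_in_order(c(1, 2)), run_in_order(c(2, 1)))
})

test_that("restarts continue the generator's private stream reproducibly", {
  params <- integrator_params(dt = 0.01, temperature = 1)
  sam <- list(reference = c(0, 0), sigma = 0.5)
  walk <- function() {
    st <- propose_initial(0L, sam, params, qbcflow:::rng_stream_new(8L))
    st <- md_step(st, c(0, 0), params)
    st <- restart_trajectory(st, sam, params)
    st
  }
  a <- walk(); b <- walk()
  expect_identical(a, b)
  expect_identical(a$restarts, 1L)
  expect_identical(a$step, 1L)  # restarts keep exploration accounting
})
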