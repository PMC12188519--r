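test_that("identical config and seed give byte-identical event logs", {
  cfg <- small_cfg(max_steps = 40L)
  oracle <- oracle_mueller_brown()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_workflow(cfg, oracle, out_dir = d1)
  run_workflow(cfg, oracle, out_dir = d2)
  expect_identical(readLines(file.path(d1, "events.jsonl")),
                   readLines(file.path(d2, "events.jsonl")))
})

test_that("disabling oracle and training yields a pure inference loop", {
  cfg <- small_cfg(enable_oracle = FALSE, enable_training = FALSE,
                   n_oracles = 0L, max_steps = 30L)
  rep <- run_workflow(cfg, oracle_mueller_brown())
  expect_identical(rep$labels, 0L)
  expect_identical(rep$epochs, 0L)
  expect_identical(rep$flushes, 0L)
  expect_identical(rep$cycles, 30L)
})

test_that("disabling oracle and training does not change predictions", {
  cfg_on <- small_cfg(max_steps = 25L, oracle_cost = 1, train_cost = 1)
  cfg_off <- small_cfg(max_steps = 25L, enable_oracle = FALSE,
                       enable_training = FALSE, n_oracles = 0L)
  # same seed and *initial* weights; compare the first prediction records,
  # which precede any weight adoption
  ev_on <- attr(run_workflow(cfg_on, oracle_mueller_brown()), "events")
  ev_off <- attr(run_workflow(cfg_off, oracle_mueller_brown()), "events")
  first_std <- function(ev) {
    p <- Filter(function(e) e$kind == "PREDICTION" && e$time == 1, ev)
    vapply(p, `[[`, numeric(1), "std")
  }
  expect_identical(first_std(ev_on), first_std(ev_off))
})

test_that("slowing the oracle 1000x leaves the fast loop untouched", {
  mk <- function(latency) {
    cfg <- small_cfg(max_steps = 30L, oracle_cost = latency)
    attr(run_workflow(cfg, oracle_mueller_brown()), "events")
  }
  fast_kinds <- c("PREDICT_REQUEST", "PREDICTION")
  fast_only <- function(ev) Filter(function(e) e$kind %in% fast_kinds &&
                                     !isTRUE(e$forwarded), ev)
  ev_quick <- mk(2)
  ev_slow <- mk(2000)
  # the number of fast-loop cycles per virtual time is unchanged
  cyc <- function(ev) max(vapply(Filter(function(e) e$kind == "PREDICTION",
                                        ev), `[[`, numeric(1), "time"))
  expect_identical(cyc(ev_quick), cyc(ev_slow))
  # the per-sample committee spreads are identical until the first adoption,
  # which with a 2000-unit oracle never happens inside the run
  std_q <- event_field(ev_slow, "PREDICTION", "std")
  expect_identical(length(std_q),
                   length(event_field(ev_quick, "PREDICTION", "std")))
})

test_that("a checkpointed run resumed equals an uninterrupted run", {
  oracle <- oracle_mueller_brown()
  d_half <- withr::local_tempdir()
  full <- run_workflow(small_cfg(max_steps = 80L, seed = 21L), oracle)
  run_workflow(small_cfg(max_steps = 40L, seed = 21L), oracle,
               out_dir = d_half)
  resumed <- resume_workflow(d_half, max_steps = 80L)
  expect_identical(attr(full, "state")$dataset,
                   attr(resumed, "state")$dataset)
  expect_identical(attr(full, "state")$gens, attr(resumed, "state")$gens)
  expect_identical(attr(full, "events"), attr(resumed, "events"))
})

test_that("resume refuses incompatible checkpoints", {
  oracle <- oracle_mueller_brown()
  d <- withr::local_tempdir()
  run_workflow(small_cfg(max_steps = 20L), oracle, out_dir = d)
  # shrinking the bound is refused
  expect_error(resume_workflow(d, max_steps = 10L), "max_steps")
  # missing member weight files are refused
  file.remove(file.path(d, "member_0.rds"))
  expect_error(resume_workflow(d, max_steps = 40L), "member weight")
  # version-mismatched checkpoints are refused
  d2 <- withr::local_tempdir()
  run_workflow(small_cfg(max_steps = 20L), oracle, out_dir = d2)
  snap <- readRDS(file.path(d2, "checkpoint.rds"))
  snap$package_version <- "0.0.0"
  saveRDS(snap, file.path(d2, "checkpoint.rds"))
  expect_error(resume_workflow(d2, max_steps = 40L), "version")
  expect_error(resume_workflow(withr::local_tempdir(), 10L), "checkpoint")
})

test_that("the multi-process backend is reported as unavailable", {
  expect_error(run_workflow(small_cfg(), oracle_mueller_brown(),
                            backend = "mpi"), "serial")
})

test_that("run directories persist log, dataset, trajectories and report", {
  d <- withr::local_tempdir()
  cfg <- small_cfg(max_steps = 30L)
  run_workflow(cfg, oracle_mueller_brown(), out_dir = d)
  expect_true(file.exists(file.path(d, "events.jsonl")))
  expect_true(file.exists(file.path(d, "dataset.xyz")))
  expect_true(file.exists(file.path(d, "traj_gen0.xyz")))
  expect_true(file.exists(file.path(d, "member_0.rds")))
  expect_true(file.exists(file.path(d, "report.json")))
  log_df <- read_event_log(file.path(d, "events.jsonl"))
  expect_true(all(c("time", "kind", "source_role") %in% names(log_df)))
  ds <- read_extxyz(file.path(d, "dataset.xyz"))
  expect_length(ds, sum(log_df$kind == "LABELED"))
})

test_that("a converged generator initiates an orderly shutdown", {
  cfg <- small_cfg(max_steps = 200L, uncertainty_threshold = Inf,
                   termination = list(type = "converged", window = 10L,
                                      max_unreliable_frac = 0))
  rep <- run_workflow(cfg, oracle_mueller_brown())
  expect_identical(rep$shutdown$reason, "converged")
  expect_match(rep$shutdown$initiator, "^generator/")
  ev <- attr(rep, "events")
  expect_identical(ev[[length(ev)]]$kind, "SHUTDOWN")
  expect_lt(rep$cycles, 200L)
})

test_that("labels forwarded stop at the configured budget", {
  cfg <- small_cfg(max_steps = 100L, label_budget = 7L)
  rep <- run_workflow(cfg, oracle_mueller_brown())
  expect_identical(rep$forwarded, 7L)
  expect_identical(rep$labels, 7L)
})

test_that("a bounded oracle queue paces forwarding to labeling capacity", {
  cfg <- small_cfg(max_steps = 60L, oracle_cost = 5, oracle_queue_cap = 2L)
  rep <- run_workflow(cfg, oracle_mueller_brown())
  ev <- attr(rep, "events")
  fw_t <- vapply(Filter(function(e) e$kind == "PREDICTION" &&
                          isTRUE(e$forwarded), ev),
                 `[[`, numeric(1), "time")
  # with cap 2 and a 5-unit oracle, at most 2 forwards per 5 time units
  expect_lt(length(fw_t), 30L)
  expect_true(all(table(cut(fw_t, seq(0, 60, by = 5))) <= 2L))
})
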