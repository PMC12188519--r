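#' @title Serial event-queue runtime
#' @description The canonical execution backend: a deterministic
#'   single-process scheduler with a virtual clock and two priority classes.
#'   The fast loop (generation--prediction) runs one cycle per virtual time
#'   unit unconditionally; slow-loop work (oracle labeling, training epochs)
#'   is queued with configurable virtual costs and processed between cycles,
#'   so slow work can never starve or perturb the fast loop except through
#'   explicit weight-adoption events. Identical configuration and seed give
#'   byte-identical event logs.
#' @name runtime
NULL

log_new <- function() {
  e <- new.env(parent = emptyenv())
  e$records <- vector("list", 256L)
  e$n <- 0L
  e
}

log_add <- function(lg, rec) {
  n <- lg$n + 1L
  if (n > length(lg$records)) {
    lg$records <- c(lg$records, vector("list", length(lg$records)))
  }
  lg$records[[n]] <- rec
  lg$n <- n
  invisible(lg)
}

log_records <- function(lg) lg$records[seq_len(lg$n)]

record <- function(time, kind, role, instance, sample_id = NA_integer_,
                   ...) {
  c(list(time = time, kind = kind, source_role = role,
         source_index = instance, sample_id = sample_id), list(...))
}

slow_push <- function(ws, time, type, payload) {
  ws$seqno <- ws$seqno + 1L
  ws$slow[[length(ws$slow) + 1L]] <-
    list(time = time, seq = ws$seqno, type = type, payload = payload)
  invisible(ws)
}

slow_pop_due <- function(ws, now) {
  if (length(ws$slow) == 0L) return(NULL)
  times <- vapply(ws$slow, `[[`, numeric(1), "time")
  seqs <- vapply(ws$slow, `[[`, numeric(1), "seq")
  ord <- order(times, seqs)
  k <- ord[1L]
  if (is.finite(now) && times[k] > now) return(NULL)
  ev <- ws$slow[[k]]
  ws$slow <- ws$slow[-k]
  ev
}

new_workflow_state <- function(cfg, oracle, selection_hook, buffer_hook,
                               trainer_criterion) {
  ws <- new.env(parent = emptyenv())
  ws$cfg <- cfg
  ws$oracle <- oracle
  ws$selection_hook <- selection_hook
  ws$buffer_hook <- buffer_hook
  ws$trainer_criterion <- trainer_criterion
  ws$params <- integrator_params(cfg$dt, cfg$friction, cfg$temperature,
                                 cfg$mass)
  ws$predictors <- committee_init(cfg)
  ws$registry <- standard_schemas(cfg, length(model_pack(ws$predictors[[1]])))
  ws$trainers <- lapply(seq_len(cfg$n_committee) - 1L,
                        function(m) trainer_init(cfg, m))
  ws$epochs_remaining <- rep(0L, cfg$n_committee)
  ws$gens <- lapply(seq_len(cfg$n_generators) - 1L, function(g) {
    propose_initial(g, cfg$sampler, ws$params,
                    rng_stream_new(derive_seed(cfg$seed, 100L + g)))
  })
  ws$gen_done <- rep(FALSE, cfg$n_generators)
  ws$obuf <- oracle_buffer_new(max(cfg$n_oracles, 1L))
  ws$tbuf <- training_buffer_new(cfg$training_buffer_threshold)
  ws$slow <- list()
  ws$seqno <- 0L
  ws$cycle <- 0L
  ws$log <- log_new()
  ws$counters <- list(forwarded = 0L, labeled = 0L, buffered = 0L,
                      flushes = 0L, duplicates = 0L, epochs = 0L,
                      exports = 0L, adoptions = 0L)
  ws$dataset <- list()
  ws$sample_counter <- 0L
  ws$shutdown <- NULL
  ws$traj_frames <- lapply(seq_len(cfg$n_generators), function(g) list())
  ws
}

oracle_total_cost <- function(ws) ws$cfg$oracle_cost + ws$oracle$latency

# dispatch idle oracles and schedule their completion events
service_oracle_buffer <- function(ws, now) {
  out <- dispatch_to_oracle(ws$obuf)
  ws$obuf <- out$buf
  for (a in out$assignments) {
    log_add(ws$log, record(now, "LABEL_REQUEST", "controller", 1L,
                           a$sample$sample_id, oracle = a$oracle_index - 1L))
    labeled <- oracle_label(ws$oracle, a$sample$coords,
                            provenance = sprintf("oracle/%d",
                                                 a$oracle_index - 1L))
    labeled$sample_id <- a$sample$sample_id
    slow_push(ws, now + oracle_total_cost(ws), "oracle_done",
              list(oracle_index = a$oracle_index, labeled = labeled))
  }
  invisible(ws)
}

do_flush <- function(ws, now, schedule_epochs = TRUE) {
  fl <- flush_training_buffer(ws$tbuf, ws$buffer_hook)
  ws$tbuf <- fl$buf
  ws$counters$flushes <- ws$counters$flushes + 1L
  log_add(ws$log, record(now, "TRAIN_BATCH", "controller", 1L,
                         batch_size = length(fl$batch)))
  if (!ws$cfg$enable_training) return(invisible(ws))
  for (m in seq_len(ws$cfg$n_committee)) {
    ws$trainers[[m]] <- ingest_batch(ws$trainers[[m]], fl$batch)
    ws$epochs_remaining[m] <- ws$cfg$epochs_per_flush
    if (schedule_epochs) {
      slow_push(ws, now + ws$cfg$train_cost, "train_epoch",
                list(member = m))
    }
  }
  invisible(ws)
}

handle_train_epoch <- function(ws, ev, reschedule = TRUE) {
  m <- ev$payload$member
  tr <- ws$trainers[[m]]
  if (tr$halted || ws$epochs_remaining[m] <= 0L ||
      length(tr$E) == 0L || !is.null(ws$shutdown)) {
    return(invisible(ws))
  }
  tr <- train_epoch(tr)
  tr <- early_stop_check(tr, ws$cfg$early_stop_patience)
  ws$counters$epochs <- ws$counters$epochs + 1L
  ws$epochs_remaining[m] <- ws$epochs_remaining[m] - 1L
  exp <- export_weights(tr, ws$cfg$weight_sync_period)
  if (!is.null(exp)) {
    ws$counters$exports <- ws$counters$exports + 1L
    log_add(ws$log, record(ev$time, "WEIGHTS", "training", m - 1L,
                           version = exp$version))
    ad <- adopt_weights(ws$predictors[[m]], exp$block, exp$version)
    if (ad$adopted) {
      ws$predictors[[m]] <- ad$member
      ws$counters$adoptions <- ws$counters$adoptions + 1L
    }
  }
  ws$trainers[[m]] <- tr
  if (training_shutdown_check(tr, ws$trainer_criterion)) {
    signal_shutdown(ws, ev$time, "training", m - 1L, "criterion")
  }
  if (reschedule && !tr$halted && ws$epochs_remaining[m] > 0L &&
      is.null(ws$shutdown)) {
    slow_push(ws, ev$time + ws$cfg$train_cost, "train_epoch",
              list(member = m))
  }
  invisible(ws)
}

handle_slow_event <- function(ws, ev, drain = FALSE) {
  if (ev$type == "oracle_done") {
    labeled <- ev$payload$labeled
    ws$obuf <- oracle_buffer_complete(ws$obuf, ev$payload$oracle_index,
                                      labeled$sample_id)
    log_add(ws$log, record(ev$time, "LABELED", "oracle",
                           ev$payload$oracle_index - 1L,
                           labeled$sample_id, energy = labeled$energy))
    ws$counters$labeled <- ws$counters$labeled + 1L
    ws$dataset[[length(ws$dataset) + 1L]] <- labeled
    cl <- collect_label(ws$tbuf, labeled)
    ws$tbuf <- cl$buf
    ws$counters$buffered <- ws$counters$buffered + 1L
    if (cl$flush_due) do_flush(ws, ev$time, schedule_epochs = !drain)
    service_oracle_buffer(ws, ev$time)
  } else if (ev$type == "train_epoch") {
    handle_train_epoch(ws, ev, reschedule = !drain)
  } else {
    stop("unknown slow event type '", ev$type, "'")
  }
  invisible(ws)
}

signal_shutdown <- function(ws, time, role, instance, reason) {
  if (!is.null(ws$shutdown)) return(invisible(ws))  # second signal ignored
  ws$shutdown <- list(initiator = sprintf("%s/%d", role, instance),
                      role = role, instance = instance,
                      reason = reason, time = time)
  invisible(ws)
}

budget_left <- function(ws) {
  is.null(ws$cfg$label_budget) ||
    ws$counters$forwarded < ws$cfg$label_budget
}

queue_has_room <- function(ws) {
  cap <- ws$cfg$oracle_queue_cap
  if (is.null(cap)) return(TRUE)
  length(ws$obuf$pending) + sum(ws$obuf$busy) < cap
}

run_fast_cycle <- function(ws) {
  cfg <- ws$cfg
  ws$cycle <- ws$cycle + 1L
  now <- as.numeric(ws$cycle)
  active <- which(!ws$gen_done)
  if (length(active) == 0L) return(invisible(ws))
  X <- do.call(rbind, lapply(ws$gens[active], `[[`, "positions"))
  cp <- committee_predict(ws$predictors, X)
  for (i in seq_along(active)) {
    if (!is.null(ws$shutdown)) break
    g <- active[i]
    st <- ws$gens[[g]]
    ws$sample_counter <- ws$sample_counter + 1L
    sid <- ws$sample_counter
    log_add(ws$log, record(now, "PREDICT_REQUEST", "generator", g - 1L, sid))
    per_E <- cp$per_model_energy[i, ]
    per_F <- do.call(rbind, lapply(cp$per_model_forces,
                                   function(f) f[i, ]))
    agg <- aggregate_predictions(per_E, per_F)
    verdict <- assess_reliability(
      list(sample_id = sid, per_model_energy = per_E,
           per_model_forces = per_F, mean_energy = agg$mean_energy,
           std_energy = agg$std_energy, mean_forces = agg$mean_forces),
      cfg$uncertainty_threshold, ws$selection_hook)
    forwarded <- FALSE
    if (verdict$label && cfg$enable_oracle && budget_left(ws) &&
        queue_has_room(ws)) {
      enq <- oracle_buffer_enqueue(
        ws$obuf, list(sample_id = sid, generator_id = g - 1L,
                      step_index = st$step, coords = st$positions))
      ws$obuf <- enq$buf
      if (enq$accepted) {
        ws$counters$forwarded <- ws$counters$forwarded + 1L
        forwarded <- TRUE
      } else {
        ws$counters$duplicates <- ws$counters$duplicates + 1L
      }
    }
    log_add(ws$log, record(now, "PREDICTION", "controller", 0L, sid,
                           std = agg$std_energy, reliable = verdict$reliable,
                           forwarded = forwarded))
    ws$traj_frames[[g]][[length(ws$traj_frames[[g]]) + 1L]] <-
      list(coords = st$positions, energy = agg$mean_energy,
           forces = agg$mean_forces, std = agg$std_energy,
           sample_id = sid)

    if (!agg$finite_ok) {
      ws$gens[[g]] <- restart_trajectory(st, cfg$sampler, ws$params)
      next
    }
    rr <- react_to_reliability(st, verdict$reliable, cfg$patience)
    st <- rr$state
    if (rr$action == "restart") {
      st <- restart_trajectory(st, cfg$sampler, ws$params)
      st$step <- st$step + 1L  # a restart consumes the step
    } else {
      st <- md_step(st, agg$mean_forces, ws$params, cfg$sampler)
      if (st$status == "restarting") {
        st <- restart_trajectory(st, cfg$sampler, ws$params)
      }
    }
    crit <- if (cfg$termination$type == "max_steps") {
      list(type = "max_steps", max_steps = cfg$max_steps)
    } else cfg$termination
    if (check_termination(st, crit)) {
      if (cfg$termination$type == "converged") {
        signal_shutdown(ws, now, "generator", g - 1L, "converged")
      }
      st$status <- "done"
      ws$gen_done[g] <- TRUE
    }
    if (st$step >= cfg$max_steps && !ws$gen_done[g]) {
      st$status <- "done"
      ws$gen_done[g] <- TRUE
    }
    ws$gens[[g]] <- st
  }
  service_oracle_buffer(ws, now)
  invisible(ws)
}

drain_slow_queue <- function(ws) {
  # complete in-flight and pending labeling work; run already-scheduled
  # training epochs but schedule no new ones
  now <- if (!is.null(ws$shutdown)) ws$shutdown$time else as.numeric(ws$cycle)
  service_oracle_buffer(ws, now)
  repeat {
    ev <- slow_pop_due(ws, Inf)
    if (is.null(ev)) break
    handle_slow_event(ws, ev, drain = TRUE)
  }
  invisible(ws)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

snapshot_state <- function(ws) {
  list(cfg = ws$cfg, oracle = ws$oracle,
       trainer_criterion = ws$trainer_criterion,
       predictors = ws$predictors, trainers = ws$trainers,
       epochs_remaining = ws$epochs_remaining,
       gens = ws$gens, gen_done = ws$gen_done,
       obuf = ws$obuf, tbuf = ws$tbuf, slow = ws$slow, seqno = ws$seqno,
       cycle = ws$cycle, log = log_records(ws$log),
       counters = ws$counters, dataset = ws$dataset,
       sample_counter = ws$sample_counter, shutdown = ws$shutdown,
       traj_frames = ws$traj_frames,
       package_version = as.character(utils::packageVersion("qbcflow")))
}

restore_state <- function(snap, selection_hook = NULL, buffer_hook = NULL) {
  ws <- new.env(parent = emptyenv())
  for (nm in setdiff(names(snap), c("log", "package_version"))) {
    ws[[nm]] <- snap[[nm]]
  }
  ws$selection_hook <- selection_hook
  ws$buffer_hook <- buffer_hook
  ws$params <- integrator_params(snap$cfg$dt, snap$cfg$friction,
                                 snap$cfg$temperature, snap$cfg$mass)
  ws$registry <- standard_schemas(snap$cfg,
                                  length(model_pack(snap$predictors[[1]])))
  ws$log <- log_new()
  for (r in snap$log) log_add(ws$log, r)
  ws
}

main_loop <- function(ws) {
  cfg <- ws$cfg
  pre_drain <- NULL
  repeat {
    # slow events due before the next cycle tick
    now <- as.numeric(ws$cycle)
    repeat {
      ev <- slow_pop_due(ws, now)
      if (is.null(ev)) break
      handle_slow_event(ws, ev)
      if (!is.null(ws$shutdown)) break
    }
    if (!is.null(ws$shutdown)) break
    if (all(ws$gen_done)) {
      pre_drain <- snapshot_state(ws)
      signal_shutdown(ws, now, "controller", 0L, "max_steps")
      break
    }
    run_fast_cycle(ws)
    if (!is.null(ws$shutdown)) break
  }
  if (is.null(pre_drain)) pre_drain <- snapshot_state(ws)
  drain_slow_queue(ws)
  # the final log record is the shutdown event naming the initiator
  log_add(ws$log, record(ws$shutdown$time, "SHUTDOWN", ws$shutdown$role,
                         ws$shutdown$instance, reason = ws$shutdown$reason))
  ws$pre_drain <- pre_drain
  invisible(ws)
}

build_report <- function(ws) {
  final_val <- vapply(ws$trainers, function(t) t$last_val %||% NA_real_,
                      numeric(1))
  final_train <- vapply(ws$trainers, function(t) t$last_train %||% NA_real_,
                        numeric(1))
  structure(list(
    cycles = ws$cycle,
    steps = vapply(ws$gens, `[[`, integer(1), "step"),
    restarts = vapply(ws$gens, `[[`, integer(1), "restarts"),
    labels = ws$counters$labeled,
    forwarded = ws$counters$forwarded,
    buffered = ws$counters$buffered,
    flushes = ws$counters$flushes,
    epochs = ws$counters$epochs,
    exports = ws$counters$exports,
    final_train_loss = final_train,
    final_val_loss = final_val,
    shutdown = ws$shutdown,
    dataset_size = length(ws$dataset)
  ), class = "qbc_report")
}

#' @export
print.qbc_report <- function(x, ...) {
  cat("<qbc_report>\n")
  cat(sprintf("  cycles=%d  steps=[%s]  restarts=[%s]\n", x$cycles,
              paste(x$steps, collapse = ","),
              paste(x$restarts, collapse = ",")))
  cat(sprintf("  labels=%d forwarded=%d buffered=%d flushes=%d epochs=%d exports=%d\n",
              x$labels, x$forwarded, x$buffered, x$flushes, x$epochs,
              x$exports))
  if (!is.null(x$shutdown)) {
    cat(sprintf("  shutdown: %s (%s) at t=%g\n", x$shutdown$initiator,
                x$shutdown$reason, x$shutdown$time))
  }
  if (any(is.finite(x$final_val_loss))) {
    cat(sprintf("  final val loss: %s\n",
                paste(signif(x$final_val_loss, 4), collapse = ", ")))
  }
  invisible(x)
}

persist_run <- function(ws, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(vapply(log_records(ws$log), function(r) {
    jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1)), file.path(out_dir, "events.jsonl"))
  if (length(ws$dataset) > 0L) {
    write_extxyz(ws$dataset, file.path(out_dir, "dataset.xyz"))
  }
  for (g in seq_along(ws$traj_frames)) {
    frames <- ws$traj_frames[[g]]
    if (length(frames) > 0L) {
      write_extxyz(frames, file.path(out_dir,
                                     sprintf("traj_gen%d.xyz", g - 1L)))
    }
  }
  for (m in seq_along(ws$predictors)) {
    saveRDS(list(architecture = list(input_dim = ws$cfg$input_dim,
                                     hidden_units = ws$cfg$hidden_units),
                 predictor = ws$predictors[[m]],
                 trainer_model = ws$trainers[[m]]$model,
                 opt = ws$trainers[[m]]$opt,
                 version = ws$predictors[[m]]$version),
            file.path(out_dir, sprintf("member_%d.rds", m - 1L)))
  }
  snap <- ws$pre_drain
  snap$trainers <- lapply(snap$trainers, function(t) {
    t  # models embedded; member files are the authoritative weight copies
  })
  saveRDS(snap, file.path(out_dir, "checkpoint.rds"))
  report <- build_report(ws)
  writeLines(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                              digits = NA, null = "null", pretty = TRUE),
             file.path(out_dir, "report.json"))
  invisible(out_dir)
}

#' Run an active-learning workflow
#'
#' Executes the full five-kernel workflow on the serial deterministic
#' backend: generators explore on committee-mean forces, the controller
#' aggregates committee predictions and thresholds their spread, unreliable
#' configurations are labeled by the oracle through a FIFO buffer, labeled
#' data accumulates in the training buffer and is flushed to all trainers at
#' the configured threshold, and trainers periodically export weights that
#' the prediction-side members adopt.
#'
#' @param cfg A validated [workflow_config()] (its `input_dim` must equal the
#'   oracle dimension).
#' @param oracle A `"qbc_oracle"` ground-truth labeler.
#' @param backend `"serial"` (the deterministic event-queue scheduler). A
#'   multi-process message-passing backend is not available in this build;
#'   [plan_ranks()] reports the process layout such a deployment would use.
#' @param out_dir Optional run directory: event log (`events.jsonl`), labeled
#'   dataset (`dataset.xyz`), per-generator trajectories, per-member
#'   checkpoints, workflow checkpoint, and exit report are written there on
#'   shutdown.
#' @param initial_dataset Optional list of labeled samples ingested (and
#'   pre-trained on) before the first cycle.
#' @param selection_hook Optional labeling-decision override,
#'   `function(prediction) -> TRUE/FALSE`; the reliability flag sent to
#'   generators is unaffected.
#' @param buffer_hook Optional training-buffer adjust hook,
#'   `function(items) -> retained items`.
#' @param trainer_criterion Optional trainer shutdown criterion,
#'   `list(val_loss_floor = x)`.
#' @return A `"qbc_report"` with the workflow state attached as attribute
#'   `"state"` (snapshot list).
#' @export
run_workflow <- function(cfg, oracle, backend = c("serial", "mpi"),
                         out_dir = NULL, initial_dataset = NULL,
                         selection_hook = NULL, buffer_hook = NULL,
                         trainer_criterion = NULL) {
  backend <- match.arg(backend)
  if (backend == "mpi") {
    stop("the multi-process MPI backend is not available in this build; ",
         "use backend = 'serial' (see plan_ranks() for the rank layout)")
  }
  cfg <- validate_config(cfg)
  stopifnot(inherits(oracle, "qbc_oracle"))
  if (cfg$input_dim != oracle$dim) {
    stop("cfg$input_dim (", cfg$input_dim, ") does not match oracle dim (",
         oracle$dim, ")")
  }
  if (cfg$n_generators < 1L) stop("at least one generator is required")
  ws <- new_workflow_state(cfg, oracle, selection_hook, buffer_hook,
                           trainer_criterion)
  if (!is.null(initial_dataset) && length(initial_dataset) > 0L &&
      cfg$enable_training) {
    for (m in seq_len(cfg$n_committee)) {
      ws$trainers[[m]] <- ingest_batch(ws$trainers[[m]], initial_dataset)
      ws$epochs_remaining[m] <- cfg$epochs_per_flush
    }
    ws$dataset <- c(ws$dataset, initial_dataset)
    for (k in seq_len(cfg$epochs_per_flush)) {
      for (m in seq_len(cfg$n_committee)) {
        handle_train_epoch(ws, list(time = 0, payload = list(member = m)),
                           reschedule = FALSE)
      }
    }
  }
  main_loop(ws)
  if (!is.null(out_dir)) persist_run(ws, out_dir)
  report <- build_report(ws)
  attr(report, "state") <- snapshot_state(ws)
  attr(report, "events") <- log_records(ws$log)
  report
}

#' Resume a checkpointed workflow
#'
#' Loads the pre-shutdown checkpoint written by a clean [run_workflow()]
#' termination and continues the event sequence as if uninterrupted under an
#' extended step bound. Refuses checkpoints written by a different package
#' version, run directories missing per-member weight files, and
#' configuration overrides that change anything except `max_steps`.
#'
#' @param run_dir Directory written by `run_workflow(out_dir = ...)`.
#' @param max_steps New (larger) per-generator step bound.
#' @param out_dir Optional directory for the resumed run's outputs.
#' @param selection_hook,buffer_hook Hooks (functions are not checkpointed).
#' @return A `"qbc_report"` for the continued run.
#' @export
resume_workflow <- function(run_dir, max_steps, out_dir = NULL,
                            selection_hook = NULL, buffer_hook = NULL) {
  ck_path <- file.path(run_dir, "checkpoint.rds")
  if (!file.exists(ck_path)) stop("no checkpoint.rds in '", run_dir, "'")
  snap <- readRDS(ck_path)
  pkg_ver <- as.character(utils::packageVersion("qbcflow"))
  if (!identical(snap$package_version, pkg_ver)) {
    stop("checkpoint written by package version ", snap$package_version,
         ", refusing to resume with version ", pkg_ver)
  }
  member_files <- file.path(run_dir,
                            sprintf("member_%d.rds",
                                    seq_len(snap$cfg$n_committee) - 1L))
  missing <- member_files[!file.exists(member_files)]
  if (length(missing) > 0L) {
    stop("missing member weight file(s): ",
         paste(basename(missing), collapse = ", "))
  }
  if (max_steps < snap$cfg$max_steps) {
    stop("resume requires max_steps >= the checkpointed bound (",
         snap$cfg$max_steps, ")")
  }
  snap$cfg$max_steps <- as.integer(max_steps)
  ws <- restore_state(snap, selection_hook, buffer_hook)
  ws$gen_done <- vapply(ws$gens, function(st) st$step >= max_steps,
                        logical(1))
  for (g in which(!ws$gen_done)) {
    if (ws$gens[[g]]$status == "done") ws$gens[[g]]$status <- "running"
  }
  ws$shutdown <- NULL
  main_loop(ws)
  if (!is.null(out_dir)) persist_run(ws, out_dir)
  report <- build_report(ws)
  attr(report, "state") <- snapshot_state(ws)
  attr(report, "events") <- log_records(ws$log)
  report
}

#' Read a line-delimited event log
#'
#' @param path Path to an `events.jsonl` written by [run_workflow()].
#' @return A data frame with one row per event (columns `time`, `kind`,
#'   `source_role`, `source_index`, `sample_id`, plus kind-specific fields).
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, function(l) jsonlite::fromJSON(l))
  events_to_df(recs)
}

events_to_df <- function(recs) {
  cols <- unique(unlist(lapply(recs, names)))
  out <- lapply(cols, function(cn) {
    vals <- lapply(recs, function(r) if (is.null(r[[cn]])) NA else r[[cn]])
    unlist(vals)
  })
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}
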