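#' @title Training kernel: per-member epoch-wise optimisation
#' @description One trainer per committee member ingests threshold-flushed
#'   batches of labeled samples, runs epoch-wise full-batch Adam on the
#'   combined energy+force loss, halts on a validation-loss early-stopping
#'   criterion, resumes when new data arrives, and exports its weights every
#'   `weight_sync_period` epochs for the corresponding prediction-side member
#'   to adopt. The validation split is a deterministic fraction of the
#'   dataset chosen by a hash of each sample id, so the split is stable as
#'   the dataset grows and never isolates the newest batch entirely in
#'   either split.
#' @name training
NULL

val_hash <- function(sample_id) {
  # multiplicative hash mapped to [0, 1); exact in double precision for ids
  # well below 2^22
  ((as.double(sample_id) * 2654435761) %% 4294967296) / 4294967296
}

#' Initialise one trainer
#'
#' @param cfg A validated [workflow_config()].
#' @param model_id Committee member id in `0..M-1`; the weight draw uses a
#'   seed derived from `(cfg$seed, model_id)`, identical to the corresponding
#'   prediction-side member.
#' @return A `"qbc_trainer"` state.
#' @export
trainer_init <- function(cfg, model_id) {
  cfg <- validate_config(cfg)
  model <- model_init(cfg$input_dim, cfg$hidden_units, seed = cfg$seed,
                      model_id = model_id)
  structure(list(model_id = as.integer(model_id),
                 model = model,
                 opt = adam_init(model),
                 X = matrix(numeric(0), 0L, cfg$input_dim),
                 E = numeric(0),
                 Fm = matrix(numeric(0), 0L, cfg$input_dim),
                 ids = integer(0),
                 epoch = 0L,
                 best_val_loss = Inf,
                 epochs_since_improvement = 0L,
                 halted = FALSE,
                 history = list(),
                 cfg = list(lr = cfg$learning_rate,
                            w_energy = cfg$w_energy, w_force = cfg$w_force,
                            val_fraction = cfg$val_fraction,
                            bootstrap = cfg$bootstrap,
                            reinitialize = cfg$reinitialize_on_new_data,
                            seed = cfg$seed,
                            input_dim = cfg$input_dim,
                            hidden_units = cfg$hidden_units)),
            class = "qbc_trainer")
}

#' Ingest a flushed batch of labeled samples
#'
#' Extends the dataset, refreshes the energy standardisation, clears the
#' halted flag (training resumes when new data arrives), and resets the
#' early-stopping counter. By default weights continue from their current
#' values — re-initialising during active learning is discouraged and off by
#' default — unless the workflow was configured with
#' `reinitialize_on_new_data = TRUE`. With `bootstrap = TRUE` each trainer
#' resamples the incoming batch with replacement using a deterministic
#' per-member seed. Duplicate coordinates are legitimate (near-identical
#' geometries from different generators) and kept.
#'
#' @param trainer A `"qbc_trainer"`.
#' @param batch Nonempty list of labeled samples (`coords`, `energy`,
#'   `forces`, `sample_id`).
#' @return The updated trainer.
#' @export
ingest_batch <- function(trainer, batch) {
  if (length(batch) == 0L) stop("cannot ingest an empty batch")
  if (isTRUE(trainer$cfg$bootstrap)) {
    out <- with_stream(
      rng_stream_new(derive_seed(trainer$cfg$seed, 7000L + trainer$model_id,
                                 length(trainer$ids))),
      function() sample.int(length(batch), length(batch), replace = TRUE))
    batch <- batch[out$value]
  }
  Xn <- do.call(rbind, lapply(batch, function(s) s$coords))
  En <- vapply(batch, `[[`, numeric(1), "energy")
  Fn <- do.call(rbind, lapply(batch, function(s) s$forces))
  idn <- vapply(batch, function(s) as.integer(s$sample_id), integer(1))
  trainer$X <- rbind(trainer$X, Xn)
  trainer$E <- c(trainer$E, En)
  trainer$Fm <- rbind(trainer$Fm, Fn)
  trainer$ids <- c(trainer$ids, idn)

  if (isTRUE(trainer$cfg$reinitialize)) {
    trainer$model <- model_init(trainer$cfg$input_dim,
                                trainer$cfg$hidden_units,
                                seed = derive_seed(trainer$cfg$seed,
                                                   length(trainer$ids)),
                                model_id = trainer$model_id)
    trainer$opt <- adam_init(trainer$model)
  }
  mu <- mean(trainer$E)
  sdv <- stats::sd(trainer$E)
  if (!is.finite(sdv) || sdv < 1e-8) sdv <- 1
  trainer$model$e_shift <- mu
  trainer$model$e_scale <- sdv
  trainer$halted <- FALSE
  trainer$best_val_loss <- Inf
  trainer$epochs_since_improvement <- 0L
  trainer
}

trainer_split <- function(trainer) {
  h <- val_hash(trainer$ids)
  val <- h < trainer$cfg$val_fraction
  if (all(val)) val[] <- FALSE  # degenerate tiny datasets train on all data
  val
}

#' Run one training epoch
#'
#' One full pass of batch Adam over the training split; deterministic given
#' the trainer state. Records train and validation loss in the history.
#'
#' @param trainer A `"qbc_trainer"` with a nonempty dataset, not halted.
#' @return The updated trainer (with `epoch` incremented and `last_train`
#'   / `last_val` losses set).
#' @export
train_epoch <- function(trainer) {
  n <- length(trainer$E)
  if (n == 0L) stop("cannot train on an empty dataset")
  if (trainer$halted) stop("trainer is halted; ingest data to resume")
  val <- trainer_split(trainer)
  tr <- !val
  sc <- trainer$model$e_scale
  Et <- (trainer$E - trainer$model$e_shift) / sc
  Ft <- trainer$Fm / sc
  lg <- model_loss_grad(trainer$model, trainer$X[tr, , drop = FALSE],
                        Et[tr], Ft[tr, , drop = FALSE],
                        trainer$cfg$w_energy, trainer$cfg$w_force)
  st <- adam_step(trainer$model, lg$grads, trainer$opt, lr = trainer$cfg$lr)
  trainer$model <- st$model
  trainer$opt <- st$opt
  trainer$epoch <- trainer$epoch + 1L
  val_loss <- if (any(val)) {
    model_loss_grad(trainer$model, trainer$X[val, , drop = FALSE],
                    Et[val], Ft[val, , drop = FALSE],
                    trainer$cfg$w_energy, trainer$cfg$w_force)$loss
  } else {
    model_loss_grad(trainer$model, trainer$X[tr, , drop = FALSE],
                    Et[tr], Ft[tr, , drop = FALSE],
                    trainer$cfg$w_energy, trainer$cfg$w_force)$loss
  }
  trainer$last_train <- lg$loss
  trainer$last_val <- val_loss
  trainer$history[[length(trainer$history) + 1L]] <-
    list(epoch = trainer$epoch, train = lg$loss, val = val_loss)
  trainer
}

#' Early-stopping check
#'
#' Halts the trainer when the validation loss has not improved for
#' `patience_epochs` consecutive epochs. Improvement resets the counter;
#' ingesting a batch clears a halt.
#'
#' @param trainer A `"qbc_trainer"` whose `last_val` is set.
#' @param patience_epochs Epoch budget without improvement, >= 1.
#' @return The updated trainer (`halted` possibly set).
#' @export
early_stop_check <- function(trainer, patience_epochs) {
  stopifnot(patience_epochs >= 1)
  if (is.null(trainer$last_val)) return(trainer)
  if (trainer$last_val < trainer$best_val_loss - 1e-12) {
    trainer$best_val_loss <- trainer$last_val
    trainer$epochs_since_improvement <- 0L
  } else {
    trainer$epochs_since_improvement <- trainer$epochs_since_improvement + 1L
  }
  if (trainer$epochs_since_improvement >= patience_epochs) {
    trainer$halted <- TRUE
  }
  trainer
}

#' Export weights on the synchronisation period
#'
#' Emits the flattened parameter block exactly when the epoch counter is a
#' positive multiple of the period; the export version is the epoch.
#'
#' @param trainer A `"qbc_trainer"`.
#' @param period Synchronisation period in epochs, >= 1.
#' @return `NULL` when the epoch is not a multiple of the period, otherwise
#'   a list with `block` and `version`.
#' @export
export_weights <- function(trainer, period) {
  stopifnot(period >= 1)
  if (trainer$epoch == 0L || trainer$epoch %% period != 0L) return(NULL)
  list(block = model_pack(trainer$model), version = trainer$epoch)
}

#' Trainer-side shutdown criterion
#'
#' Demo criterion: validation loss at or below a floor. Absent criterion
#' never signals.
#'
#' @param trainer A `"qbc_trainer"`.
#' @param criterion `NULL` or `list(val_loss_floor = x)`.
#' @return `TRUE` when the criterion holds.
#' @export
training_shutdown_check <- function(trainer, criterion = NULL) {
  if (is.null(criterion) || is.null(criterion$val_loss_floor)) return(FALSE)
  !is.null(trainer$last_val) && trainer$last_val <= criterion$val_loss_floor
}
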