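test_that("a single labeled point is interpolated to negligible loss", {
  cfg <- small_cfg()
  tr <- trainer_init(cfg, 0L)
  tr <- ingest_batch(tr, bowl_dataset(1))
  for (k in 1:500) tr <- train_epoch(tr)
  expect_lt(tr$last_train, 1e-6)
})

test_that("loss is non-increasing for most consecutive epochs on fixed data", {
  cfg <- small_cfg(learning_rate = 0.005)
  tr <- trainer_init(cfg, 0L)
  tr <- ingest_batch(tr, bowl_dataset(30))
  losses <- numeric(200)
  for (k in 1:200) {
    tr <- train_epoch(tr)
    losses[k] <- tr$last_train
  }
  frac_down <- mean(diff(losses) <= 0)
  expect_gte(frac_down, 0.95)
})

test_that("training is deterministic given seed and data", {
  cfg <- small_cfg()
  run <- function() {
    tr <- trainer_init(cfg, 1L)
    tr <- ingest_batch(tr, bowl_dataset(15))
    for (k in 1:40) tr <- train_epoch(tr)
    tr$model
  }
  expect_identical(run(), run())
})

test_that("ingest clears a halt and keeps weights by default", {
  cfg <- small_cfg()
  tr <- trainer_init(cfg, 0L)
  tr <- ingest_batch(tr, bowl_dataset(10))
  for (k in 1:10) tr <- train_epoch(tr)
  tr$halted <- TRUE
  w_before <- tr$model[c("W1", "b1", "w2", "b2")]
  tr <- ingest_batch(tr, bowl_dataset(5, seed = 2L))
  expect_false(tr$halted)
  expect_identical(tr$model[c("W1", "b1", "w2", "b2")], w_before)
  expect_identical(tr$epochs_since_improvement, 0L)
  expect_error(ingest_batch(tr, list()), "empty batch")
})

test_that("reinitialize_on_new_data redraws weights at ingest", {
  cfg <- small_cfg(reinitialize_on_new_data = TRUE)
  tr <- trainer_init(cfg, 0L)
  tr <- ingest_batch(tr, bowl_dataset(10))
  for (k in 1:10) tr <- train_epoch(tr)
  w_before <- tr$model$W1
  tr <- ingest_batch(tr, bowl_dataset(5, seed = 2L))
  expect_false(identical(tr$model$W1, w_before))
})

test_that("early stopping halts exactly at the configured patience", {
  cfg <- small_cfg()
  tr <- trainer_init(cfg, 0L)
  tr$best_val_loss <- 1
  # scripted flat validation sequence: no improvement ever
  halted_at <- NA_integer_
  for (k in 1:20) {
    tr$last_val <- 1
    tr <- early_stop_check(tr, 10L)
    if (tr$halted) { halted_at <- k; break }
  }
  expect_identical(halted_at, 10L)

  # strict improvement never halts
  tr2 <- trainer_init(cfg, 0L)
  tr2$best_val_loss <- Inf
  for (k in 1:50) {
    tr2$last_val <- 1 / k
    tr2 <- early_stop_check(tr2, 3L)
  }
  expect_false(tr2$halted)

  # ingesting a batch resumes a halted trainer
  tr <- ingest_batch(tr, bowl_dataset(3))
  expect_false(tr$halted)
  expect_silent(train_epoch(tr))
})

test_that("weight exports land exactly on multiples of the sync period", {
  cfg <- small_cfg()
  tr <- trainer_init(cfg, 0L)
  tr <- ingest_batch(tr, bowl_dataset(10))
  exported <- integer(0)
  for (k in 1:12) {
    tr <- train_epoch(tr)
    ex <- export_weights(tr, 5L)
    if (!is.null(ex)) exported <- c(exported, ex$version)
  }
  expect_identical(exported, c(5L, 10L))
  # period 1 exports every epoch
  expect_identical(export_weights(tr, 1L)$version, tr$epoch)
  # epoch 0 never exports
  expect_null(export_weights(trainer_init(cfg, 0L), 1L))
})

test_that("trainer shutdown criterion fires on the loss floor only", {
  cfg <- small_cfg()
  tr <- trainer_init(cfg, 0L)
  expect_false(training_shutdown_check(tr, NULL))
  tr$last_val <- 0.5
  expect_false(training_shutdown_check(tr, list(val_loss_floor = 0.1)))
  tr$last_val <- 0.05
  expect_true(training_shutdown_check(tr, list(val_loss_floor = 0.1)))
})

test_that("the validation split is a stable deterministic hash of sample ids", {
  cfg <- small_cfg(val_fraction = 0.3)
  tr <- trainer_init(cfg, 0L)
  tr <- ingest_batch(tr, bowl_dataset(50))
  split1 <- qbcflow:::trainer_split(tr)
  tr2 <- ingest_batch(tr, bowl_dataset(20, seed = 5L))
  split2 <- qbcflow:::trainer_split(tr2)
  # earlier samples keep their assignment as the dataset grows
  expect_identical(split2[1:50], split1)
})

test_that("parameter gradients of the combined loss pass finite differences", {
  m <- model_init(2L, 6L, seed = 2L, model_id = 0L)
  set.seed(4)
  X <- matrix(stats::rnorm(10), 5, 2)
  Et <- stats::rnorm(5)
  Ft <- matrix(stats::rnorm(10), 5, 2)
  lg <- qbcflow:::model_loss_grad(m, X, Et, Ft, w_energy = 1, w_force = 0.3)
  h <- 1e-6
  for (field in c("W1", "b1", "w2", "b2")) {
    idx <- 1L
    m2 <- m; m2[[field]][idx] <- m2[[field]][idx] + h
    up <- qbcflow:::model_loss_grad(m2, X, Et, Ft, 1, 0.3)$loss
    m2[[field]][idx] <- m2[[field]][idx] - 2 * h
    dn <- qbcflow:::model_loss_grad(m2, X, Et, Ft, 1, 0.3)$loss
    expect_equal(lg$grads[[field]][idx], (up - dn) / (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("bootstrap resampling diversifies trainers beyond initialisation", {
  cfg <- small_cfg(bootstrap = TRUE, n_committee = 2L)
  ds <- bowl_dataset(20)
  t0 <- ingest_batch(trainer_init(cfg, 0L), ds)
  t1 <- ingest_batch(trainer_init(cfg, 1L), ds)
  expect_false(identical(t0$E, t1$E))
  expect_identical(length(t0$E), 20L)
})
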