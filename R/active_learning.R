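#' @title End-to-end demo studies
#' @description Self-contained studies on the closed-form demo oracles: an
#'   uncertainty-driven active-learning run on the Mueller-Brown surface
#'   compared against a random-sampling baseline under an identical oracle
#'   budget and model, and committee recovery of the Lennard-Jones dimer well
#'   from oracle-labeled geometries. These are the package's scientific
#'   probes: the active-learning machinery must produce training sets that
#'   beat blind sampling, and the surrogate must recover known physical
#'   landmarks.
#' @name demos
NULL

#' Train a fresh committee on a fixed labeled dataset
#'
#' Used for head-to-head dataset comparisons: initialisation seeds, loss and
#' optimiser are identical across datasets, so any accuracy difference is
#' attributable to the data.
#'
#' Each member returns the weights of its *best validation epoch*, not the
#' final one: full-batch Adam oscillates late in training, and the last
#' snapshot can be far off the best model seen (standard early stopping
#' with best-weights restoration).
#'
#' @param dataset List of labeled samples.
#' @param cfg A validated [workflow_config()] (supplies architecture, loss
#'   weights, learning rate, committee size, seed).
#' @param epochs Maximum training epochs per member.
#' @param early_stop Early-stopping patience (epochs without validation
#'   improvement); `Inf` trains the full schedule (the best-epoch weights
#'   are still the ones returned).
#' @return List of trained `"qbc_model"` members.
#' @export
train_committee <- function(dataset, cfg, epochs = 800L, early_stop = 50L) {
  cfg <- validate_config(cfg)
  lapply(seq_len(cfg$n_committee) - 1L, function(m) {
    tr <- trainer_init(cfg, m)
    tr <- ingest_batch(tr, dataset)
    best_val <- Inf
    best_model <- tr$model
    for (k in seq_len(epochs)) {
      tr <- train_epoch(tr)
      if (tr$last_val < best_val) {
        best_val <- tr$last_val
        best_model <- tr$model
      }
      if (is.finite(early_stop)) {
        tr <- early_stop_check(tr, early_stop)
        if (tr$halted) break
      }
    }
    best_model
  })
}

#' Committee-mean error on a Mueller-Brown evaluation grid
#'
#' A fixed `nx` x `ny` grid over the standard viewing box, restricted to the
#' valley region (true energy at or below `energy_cutoff`, excluding the
#' steep repulsive walls). When `boltzmann_temperature` is given, grid
#' points are weighted by the Boltzmann factor
#' \eqn{w_i \propto \exp(-V_i / T)} before the root-mean-square error is
#' taken: a potential destined for dynamics at temperature T is judged on
#' the configurations the thermal ensemble at T actually visits, which is
#' the standard quality measure for machine-learned potentials.
#'
#' @param committee List of `"qbc_model"` members.
#' @param oracle A Mueller-Brown oracle.
#' @param nx,ny Grid resolution.
#' @param xlim,ylim Grid box.
#' @param energy_cutoff Only grid points with true energy `<= energy_cutoff`
#'   enter the error.
#' @param boltzmann_temperature Optional reduced temperature for
#'   Boltzmann-weighting the squared errors; `NULL` weighs all retained grid
#'   points equally.
#' @return List with `rmse`, `n_points`, and the grid data frame.
#' @export
mb_grid_rmse <- function(committee, oracle, nx = 50L, ny = 50L,
                         xlim = c(-1.5, 1.2), ylim = c(-0.2, 2.0),
                         energy_cutoff = 0, boltzmann_temperature = NULL) {
  gx <- seq(xlim[1], xlim[2], length.out = nx)
  gy <- seq(ylim[1], ylim[2], length.out = ny)
  G <- as.matrix(expand.grid(x = gx, y = gy))
  truth <- mb_energy_grid(oracle, G)
  keep <- truth <= energy_cutoff
  pred <- committee_predict(committee, G[keep, , drop = FALSE])$mean_energy
  err <- pred - truth[keep]
  w <- if (is.null(boltzmann_temperature)) {
    rep(1, sum(keep))
  } else {
    v <- truth[keep]
    exp(-(v - min(v)) / boltzmann_temperature)
  }
  list(rmse = sqrt(sum(w * err^2) / sum(w)), n_points = sum(keep),
       grid = data.frame(x = G[keep, 1], y = G[keep, 2],
                         truth = truth[keep], pred = pred, weight = w))
}

mb_demo_config <- function(seed, label_budget, n_committee = 4L) {
  workflow_config(
    n_generators = 4L, n_committee = n_committee, n_oracles = 4L,
    input_dim = 2L, uncertainty_threshold = 1, patience = 2L,
    training_buffer_threshold = 16L, weight_sync_period = 5L,
    early_stop_patience = 25L, max_steps = 1200L,
    seed = seed, dt = 0.005, friction = 2, temperature = 15, mass = 1,
    sampler = list(type = "uniform", lower = c(-1.5, -0.2),
                   upper = c(1.2, 2.0)),
    hidden_units = 32L, learning_rate = 0.02, w_energy = 1, w_force = 0.1,
    epochs_per_flush = 30L, oracle_cost = 4, train_cost = 0.5,
    label_budget = label_budget, oracle_queue_cap = 8L
  )
}

#' Uncertainty-driven active learning on the Mueller-Brown surface
#'
#' Runs the full workflow with a fixed oracle budget: `n_initial` seed labels
#' drawn from the initial-condition sampler, then surrogate-driven Langevin
#' exploration with query-by-committee selection until the remaining budget
#' is spent (or the step bound is hit). A fresh committee is then trained on
#' the resulting dataset and evaluated on the fixed grid.
#'
#' Oracle labels with true energy above `energy_cap` are excluded from the
#' training set (they sit on the steep repulsive walls, where force
#' magnitudes reach thousands of reduced units and would dominate the loss);
#' the labels still count against the budget — paying for occasional wall
#' excursions is the honest cost of exploration. The same cap bounds the
#' random baseline's rejection sampling, so both arms train on the same
#' energy range.
#'
#' @param seed Integer seed.
#' @param label_budget Total oracle labels (seed labels included).
#' @param n_initial Seed labels drawn from the sampler before exploration.
#' @param n_committee Committee size M.
#' @param energy_cap Training-set filter: labels above this true energy are
#'   paid for but not trained on.
#' @param final_epochs,final_early_stop Training protocol for the fresh
#'   evaluation committee.
#' @return List with `rmse`, `dataset`, `report`, `committee`.
#' @export
demo_mb_active_learning <- function(seed, label_budget = 300L,
                                    n_initial = 20L, n_committee = 4L,
                                    energy_cap = 100,
                                    final_epochs = 3000L,
                                    final_early_stop = 300L) {
  oracle <- oracle_mueller_brown()
  cfg <- mb_demo_config(seed, label_budget = label_budget - n_initial,
                        n_committee = n_committee)
  stream <- rng_stream_new(derive_seed(seed, 42L))
  init <- with_stream(stream, function() {
    lapply(seq_len(n_initial), function(i) {
      x <- stats::runif(2, cfg$sampler$lower, cfg$sampler$upper)
      s <- oracle_label(oracle, x, provenance = "initial")
      s$sample_id <- -i
      s
    })
  })$value
  report <- run_workflow(cfg, oracle, initial_dataset = init)
  dataset <- attr(report, "state")$dataset
  train_set <- Filter(function(s) s$energy <= energy_cap, dataset)
  committee <- train_committee(train_set, cfg, epochs = final_epochs,
                               early_stop = final_early_stop)
  ev <- mb_grid_rmse(committee, oracle)
  list(rmse = ev$rmse, dataset = dataset, report = report,
       committee = committee, n_labels = length(dataset))
}

#' Random-sampling baseline on the Mueller-Brown surface
#'
#' Labels `label_budget` configurations drawn uniformly over the exploration
#' box — every draw is an oracle call and is charged against the budget,
#' exactly as in the active arm — then trains the identical committee with
#' the identical protocol on the identically filtered (true energy at most
#' `energy_cap`) subset.
#'
#' @inheritParams demo_mb_active_learning
#' @return List with `rmse`, `dataset`, `committee`.
#' @export
demo_mb_random_baseline <- function(seed, label_budget = 300L,
                                    n_committee = 4L, energy_cap = 100,
                                    final_epochs = 3000L,
                                    final_early_stop = 300L) {
  oracle <- oracle_mueller_brown()
  cfg <- mb_demo_config(seed, label_budget = label_budget,
                        n_committee = n_committee)
  lo <- cfg$sampler$lower; hi <- cfg$sampler$upper
  stream <- rng_stream_new(derive_seed(seed, 77L))
  dataset <- with_stream(stream, function() {
    lapply(seq_len(label_budget), function(i) {
      s <- oracle_label(oracle, stats::runif(2, lo, hi),
                        provenance = "random")
      s$sample_id <- i
      s
    })
  })$value
  train_set <- Filter(function(s) s$energy <= energy_cap, dataset)
  committee <- train_committee(train_set, cfg, epochs = final_epochs,
                               early_stop = final_early_stop)
  ev <- mb_grid_rmse(committee, oracle)
  list(rmse = ev$rmse, dataset = dataset, committee = committee)
}

#' Compare active learning against random labeling over several seeds
#'
#' @param seeds Integer vector of run seeds (one paired comparison each).
#' @param label_budget Oracle budget shared by both arms.
#' @param ... Passed to the two demo drivers.
#' @return Data frame with per-seed RMSEs and the two medians as attributes
#'   `median_al` / `median_random`.
#' @export
compare_al_vs_random <- function(seeds = 1:5, label_budget = 300L, ...) {
  rows <- lapply(seeds, function(s) {
    al <- demo_mb_active_learning(s, label_budget = label_budget, ...)
    rnd <- demo_mb_random_baseline(s, label_budget = label_budget, ...)
    data.frame(seed = s, rmse_al = al$rmse, rmse_random = rnd$rmse,
               n_labels_al = al$n_labels)
  })
  out <- do.call(rbind, rows)
  attr(out, "median_al") <- stats::median(out$rmse_al)
  attr(out, "median_random") <- stats::median(out$rmse_random)
  out
}

#' Lennard-Jones dimer sampling
#'
#' Canonical dimer geometries: particle 1 at the origin, particle 2 at
#' separation r along x, with r drawn uniformly from `r_range` (in units of
#' sigma).
#'
#' @param n Number of geometries.
#' @param seed Integer seed.
#' @param oracle A Lennard-Jones oracle with `n = 2`.
#' @param r_range Separation range in units of sigma.
#' @return List of labeled samples.
#' @export
lj_dimer_dataset <- function(n, seed, oracle = oracle_lennard_jones(),
                             r_range = c(0.9, 2.5)) {
  sigma <- oracle$params$sigma
  out <- with_stream(rng_stream_new(derive_seed(seed, 9L)), function() {
    r <- stats::runif(n, r_range[1] * sigma, r_range[2] * sigma)
    lapply(seq_len(n), function(i) {
      s <- oracle_label(oracle, c(0, 0, 0, r[i], 0, 0),
                        provenance = "dimer_scan")
      s$sample_id <- i
      s
    })
  })
  out$value
}

#' Recover the Lennard-Jones well from a trained committee
#'
#' Trains a committee on oracle-labeled dimer geometries and reads the well
#' depth and minimum location off the committee-mean energy curve on a dense
#' separation grid. The physical references are depth `-epsilon` at
#' separation `2^(1/6) * sigma`.
#'
#' Early stopping is disabled by default here: the combined energy+force
#' loss passes through a non-monotone warm-up phase (validation loss rises
#' for tens of epochs while the network reorganises) that would trigger a
#' premature halt, and on a fixed dataset the full schedule is cheap.
#'
#' @param seed Integer seed.
#' @param n_samples Training geometries (>= 200 for the standard probe).
#' @param epochs,early_stop Training protocol.
#' @return List with `depth`, `r_min`, `depth_rel_err`, `r_min_rel_err`,
#'   `committee`, `curve` (data frame r, energy).
#' @export
demo_lj_dimer_recovery <- function(seed, n_samples = 220L, epochs = 1500L,
                                   early_stop = Inf) {
  oracle <- oracle_lennard_jones()
  eps <- oracle$params$epsilon; sigma <- oracle$params$sigma
  dataset <- lj_dimer_dataset(n_samples, seed, oracle)
  cfg <- workflow_config(
    n_generators = 1L, n_committee = 4L, n_oracles = 1L, input_dim = 6L,
    uncertainty_threshold = 0.1, patience = 2L, seed = seed,
    hidden_units = 32L, learning_rate = 0.02, w_energy = 1, w_force = 0.2,
    sampler = list(reference = numeric(6), sigma = 0.1)
  )
  committee <- train_committee(dataset, cfg, epochs = epochs,
                               early_stop = early_stop)
  r_grid <- seq(1.0 * sigma, 1.6 * sigma, length.out = 601)
  X <- cbind(0, 0, 0, r_grid, 0, 0)
  mean_E <- committee_predict(committee, X)$mean_energy
  k <- which.min(mean_E)
  depth <- mean_E[k]; r_min <- r_grid[k]
  list(depth = depth, r_min = r_min,
       depth_rel_err = abs(depth - (-eps)) / eps,
       r_min_rel_err = abs(r_min - 2^(1 / 6) * sigma) / (2^(1 / 6) * sigma),
       committee = committee,
       curve = data.frame(r = r_grid, energy = mean_E))
}
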