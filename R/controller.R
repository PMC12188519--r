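#' @title Controller kernel: aggregation, reliability, buffers, dispatch
#' @description The controller owns every routing decision in the workflow.
#'   It aggregates committee outputs into a mean/spread summary, decides
#'   reliability against the uncertainty threshold, maintains the oracle input
#'   buffer (FIFO, first-available-oracle dispatch) and the training data
#'   buffer (threshold-triggered flush to all trainers), and propagates
#'   shutdown. Neither generators nor predictors ever decide reliability
#'   themselves; they only receive the controller's verdict.
#' @name controller
NULL

#' Aggregate per-member predictions into a committee summary
#'
#' Mean and population (divide-by-M) standard deviation over the model axis;
#' forces are averaged componentwise. A non-finite member output marks the
#' sample unreliable rather than poisoning downstream arithmetic.
#'
#' @param per_model_energy Numeric vector of length M.
#' @param per_model_forces M x D matrix (row per member).
#' @return List with `mean_energy`, `std_energy`, `mean_forces`, and logical
#'   `finite_ok`.
#' @export
aggregate_predictions <- function(per_model_energy, per_model_forces) {
  M <- length(per_model_energy)
  stopifnot(M >= 1L)
  if (is.null(dim(per_model_forces))) {
    per_model_forces <- matrix(per_model_forces, nrow = M)
  }
  stopifnot(nrow(per_model_forces) == M)
  finite_ok <- all(is.finite(per_model_energy)) &&
    all(is.finite(per_model_forces))
  if (!finite_ok) {
    D <- ncol(per_model_forces)
    return(list(mean_energy = NA_real_, std_energy = Inf,
                mean_forces = rep(NA_real_, D), finite_ok = FALSE))
  }
  mu <- mean(per_model_energy)
  std <- sqrt(mean((per_model_energy - mu)^2))
  list(mean_energy = mu, std_energy = std,
       mean_forces = colMeans(per_model_forces), finite_ok = TRUE)
}

#' Decide reliability and labeling for one committee prediction
#'
#' The reliability flag sent back to generators always follows the default
#' rule `std_energy <= threshold` (boundary equality counts as reliable,
#' since forwarding happens only when the spread *exceeds* the threshold).
#' A user selection hook, when given, overrides the labeling decision only;
#' hook errors abort the run rather than being silently swallowed.
#'
#' @param pred Committee summary (needs `std_energy`; the full prediction is
#'   passed to the hook).
#' @param threshold Uncertainty threshold, >= 0.
#' @param hook Optional `function(pred) -> logical` labeling override.
#' @return List with logicals `reliable` and `label`.
#' @export
assess_reliability <- function(pred, threshold, hook = NULL) {
  stopifnot(threshold >= 0)
  reliable <- is.finite(pred$std_energy) && pred$std_energy <= threshold
  label <- !reliable
  if (!is.null(hook)) {
    res <- hook(pred)
    if (!is.logical(res) || length(res) != 1L || is.na(res)) {
      stop("selection hook must return a single TRUE/FALSE")
    }
    label <- res
  }
  list(reliable = reliable, label = label)
}

#' Oracle input buffer
#'
#' FIFO of samples awaiting ground-truth labels plus the per-oracle busy
#' table. Duplicate sample ids (already pending or in flight) are ignored on
#' enqueue so no sample is ever labeled twice.
#'
#' @param n_oracles Number of oracle instances.
#' @return A `"qbc_obuf"` list.
#' @export
oracle_buffer_new <- function(n_oracles) {
  structure(list(pending = list(),
                 busy = rep(FALSE, n_oracles),
                 inflight = vector("list", n_oracles),
                 seen_ids = integer(0)),
            class = "qbc_obuf")
}

#' @param buf A `"qbc_obuf"`.
#' @param sample List with at least `sample_id` and `coords`.
#' @return List with the updated buffer and logical `accepted` (`FALSE` for a
#'   duplicate id).
#' @rdname oracle_buffer_new
#' @export
oracle_buffer_enqueue <- function(buf, sample) {
  if (sample$sample_id %in% buf$seen_ids) {
    return(list(buf = buf, accepted = FALSE))
  }
  buf$pending[[length(buf$pending) + 1L]] <- sample
  buf$seen_ids <- c(buf$seen_ids, sample$sample_id)
  list(buf = buf, accepted = TRUE)
}

#' Dispatch pending samples to idle oracles
#'
#' While any oracle is idle and the FIFO is nonempty, the head of the queue
#' goes to the lowest-index idle oracle, which is marked busy. A no-op when
#' there is nothing to do.
#'
#' @param buf A `"qbc_obuf"`.
#' @return List with the updated buffer and `assignments`, a list of
#'   `list(oracle_index, sample)` pairs made in this call.
#' @export
dispatch_to_oracle <- function(buf) {
  assignments <- list()
  repeat {
    idle <- which(!buf$busy)
    if (length(idle) == 0L || length(buf$pending) == 0L) break
    k <- idle[1L]
    sample <- buf$pending[[1L]]
    buf$pending <- buf$pending[-1L]
    buf$busy[k] <- TRUE
    buf$inflight[[k]] <- sample
    assignments[[length(assignments) + 1L]] <-
      list(oracle_index = k, sample = sample)
  }
  list(buf = buf, assignments = assignments)
}

#' Mark an oracle's in-flight sample as completed
#'
#' @param buf A `"qbc_obuf"`.
#' @param oracle_index Index of the oracle returning a label.
#' @param sample_id Id of the labeled sample; must match the in-flight record
#'   (anything else indicates ledger corruption and is an error).
#' @return The updated buffer.
#' @export
oracle_buffer_complete <- function(buf, oracle_index, sample_id) {
  rec <- buf$inflight[[oracle_index]]
  if (!buf$busy[oracle_index] || is.null(rec) ||
      rec$sample_id != sample_id) {
    stop("label returned for sample ", sample_id,
         " which oracle ", oracle_index, " was not computing")
  }
  buf$busy[oracle_index] <- FALSE
  buf$inflight[oracle_index] <- list(NULL)
  buf
}

#' Training data buffer
#'
#' Accumulates labeled samples; a flush is due exactly when the item count
#' reaches the configured threshold.
#'
#' @param threshold Flush threshold, >= 1.
#' @return A `"qbc_tbuf"` list.
#' @export
training_buffer_new <- function(threshold) {
  stopifnot(threshold >= 1)
  structure(list(items = list(), threshold = as.integer(threshold)),
            class = "qbc_tbuf")
}

#' Store a returned label in the training data buffer
#'
#' @param buf A `"qbc_tbuf"`.
#' @param labeled A labeled sample (from [oracle_label()], with `sample_id`).
#' @return List with the updated buffer and logical `flush_due`.
#' @export
collect_label <- function(buf, labeled) {
  buf$items[[length(buf$items) + 1L]] <- labeled
  list(buf = buf, flush_due = length(buf$items) >= buf$threshold)
}

#' Flush the training data buffer
#'
#' Returns the identical batch that is broadcast to every trainer (committee
#' members see the same data and differ by initialisation). By default the
#' buffer is emptied; a user adjust hook may retain items (e.g. keep the
#' newest k) for the next flush.
#'
#' @param buf A `"qbc_tbuf"` at or above its threshold.
#' @param hook Optional `function(items) -> retained items` buffer-adjust
#'   hook; must return a (possibly empty) subset-like list.
#' @return List with `batch` (the flushed items) and the updated `buf`.
#' @export
flush_training_buffer <- function(buf, hook = NULL) {
  if (length(buf$items) < buf$threshold) {
    stop("flush requested below threshold (", length(buf$items), " < ",
         buf$threshold, ")")
  }
  batch <- buf$items
  retained <- if (is.null(hook)) list() else hook(buf$items)
  if (!is.list(retained)) stop("buffer-adjust hook must return a list")
  buf$items <- retained
  list(batch = batch, buf = buf)
}
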