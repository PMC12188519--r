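#' @title Fixed-shape message contract
#' @description Kernels exchange typed messages whose payload shapes are
#'   registered once at startup; this mirrors the constraint that efficient
#'   message-passing transports want predetermined buffer sizes. A message of
#'   an unregistered kind, or with a payload that does not match the
#'   registered shape exactly, is rejected.
#' @name messages
NULL

MESSAGE_KINDS <- c("PREDICT_REQUEST", "PREDICTION", "LABEL_REQUEST",
                   "LABELED", "TRAIN_BATCH", "WEIGHTS", "SHUTDOWN",
                   "HEARTBEAT")

KERNEL_ROLES <- c("prediction", "generator", "training", "oracle",
                  "controller")

#' Create an empty message-schema registry
#'
#' @return An environment-backed registry of class `"qbc_registry"` mapping
#'   message kinds to payload shapes (integer dimension vectors).
#' @export
schema_registry <- function() {
  reg <- new.env(parent = emptyenv())
  structure(list(shapes = reg), class = "qbc_registry")
}

#' Register the payload shape for a message kind
#'
#' Must be called during startup, before any message of that kind is built.
#' Re-registering a kind with a different shape is an error; re-registering
#' with the identical shape is a no-op.
#'
#' @param registry A [schema_registry()].
#' @param kind One of `r paste(MESSAGE_KINDS, collapse = ", ")`.
#' @param shape Integer vector of payload dimensions (a scalar payload is
#'   shape `1`).
#' @return The registry, invisibly.
#' @export
register_schema <- function(registry, kind, shape) {
  stopifnot(inherits(registry, "qbc_registry"))
  kind <- match.arg(kind, MESSAGE_KINDS)
  shape <- as.integer(shape)
  if (any(shape < 1L) || length(shape) == 0L) {
    stop("payload shape must be a vector of positive dimensions")
  }
  existing <- registry$shapes[[kind]]
  if (!is.null(existing) && !identical(existing, shape)) {
    stop("message kind '", kind, "' already registered with shape (",
         paste(existing, collapse = ","), "); cannot re-register as (",
         paste(shape, collapse = ","), ")")
  }
  assign(kind, shape, envir = registry$shapes)
  invisible(registry)
}

#' Kernel identity
#'
#' Every kernel process is identified by its role, its instance index within
#' that role, and (in a multi-process deployment) its rank.
#'
#' @param role One of `r paste(KERNEL_ROLES, collapse = ", ")`.
#' @param instance_index Zero-based index among instances of the same role.
#' @param rank Process rank; `NA` in the serial backend.
#' @return A `"qbc_identity"` list.
#' @export
kernel_identity <- function(role, instance_index, rank = NA_integer_) {
  role <- match.arg(role, KERNEL_ROLES)
  stopifnot(instance_index >= 0)
  structure(list(role = role, instance_index = as.integer(instance_index),
                 rank = as.integer(rank)),
            class = "qbc_identity")
}

#' @export
format.qbc_identity <- function(x, ...) {
  sprintf("%s/%d", x$role, x$instance_index)
}

#' @export
print.qbc_identity <- function(x, ...) {
  cat("<kernel ", format(x), ">\n", sep = "")
  invisible(x)
}

payload_shape <- function(payload) {
  d <- dim(payload)
  if (is.null(d)) length(payload) else as.integer(d)
}

#' Build a message, enforcing the registered payload shape
#'
#' @param registry A [schema_registry()] with the kind already registered.
#' @param kind Message kind tag.
#' @param source The sending [kernel_identity()].
#' @param payload Numeric vector/matrix/array whose shape must equal the
#'   registered shape for `kind`.
#' @return A `"qbc_message"` list with fields `kind`, `source`, `payload`.
#' @export
make_message <- function(registry, kind, source, payload) {
  stopifnot(inherits(registry, "qbc_registry"),
            inherits(source, "qbc_identity"))
  if (!kind %in% MESSAGE_KINDS) {
    stop("unknown message kind '", kind, "'")
  }
  expected <- registry$shapes[[kind]]
  if (is.null(expected)) {
    stop("message kind '", kind, "' has no registered payload schema")
  }
  got <- payload_shape(payload)
  if (!identical(got, expected)) {
    stop("payload shape mismatch for kind '", kind, "': expected (",
         paste(expected, collapse = ","), "), got (",
         paste(got, collapse = ","), ")")
  }
  if (!all(is.finite(payload) | is.na(payload))) {
    stop("message payload contains non-finite, non-NA entries")
  }
  structure(list(kind = kind, source = source, payload = payload),
            class = "qbc_message")
}

#' Plan the process layout of a multi-process deployment
#'
#' Computes the bijective assignment of kernel identities to ranks that a
#' message-passing launch would use: all generators, then the M prediction
#' members, then the M trainers, then the oracles, then the two controller
#' sub-kernels (fast generation--prediction loop and slow oracle--training
#' loop).
#'
#' @param cfg A validated [workflow_config()].
#' @return A data frame with columns `role`, `instance_index`, `rank`.
#' @export
plan_ranks <- function(cfg) {
  cfg <- validate_config(cfg)
  roles <- c(rep("generator", cfg$n_generators),
             rep("prediction", cfg$n_committee),
             rep("training", cfg$n_committee),
             rep("oracle", cfg$n_oracles),
             rep("controller", 2L))
  idx <- sequence(c(cfg$n_generators, cfg$n_committee, cfg$n_committee,
                    cfg$n_oracles, 2L)) - 1L
  data.frame(role = roles, instance_index = idx,
             rank = seq_along(roles) - 1L, stringsAsFactors = FALSE)
}

#' Register the standard message schemas for a configuration
#'
#' Shapes follow the workflow's data records: a predict request carries one
#' coordinate vector (D), a prediction carries the per-member energies plus
#' mean/std and the mean forces ((M + 3) + D values), a label request carries
#' D coordinates, a labeled sample carries D coordinates, one energy and D
#' forces, a weight message carries the flattened parameter block.
#'
#' @param cfg A validated [workflow_config()].
#' @param n_params Length of a committee member's flattened parameter block.
#' @return A populated [schema_registry()].
#' @export
standard_schemas <- function(cfg, n_params) {
  cfg <- validate_config(cfg)
  D <- cfg$input_dim
  M <- cfg$n_committee
  reg <- schema_registry()
  register_schema(reg, "PREDICT_REQUEST", D)
  register_schema(reg, "PREDICTION", M + 3L + D)
  register_schema(reg, "LABEL_REQUEST", D)
  register_schema(reg, "LABELED", 2L * D + 1L)
  register_schema(reg, "TRAIN_BATCH",
                  c(cfg$training_buffer_threshold, 2L * D + 1L))
  register_schema(reg, "WEIGHTS", as.integer(n_params))
  register_schema(reg, "SHUTDOWN", 1L)
  register_schema(reg, "HEARTBEAT", 1L)
  reg
}
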