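#' @title Committee surrogate model
#' @description The demo machine-learned potential is a single-hidden-layer
#'   tanh network mapping a flattened coordinate vector to a scalar energy;
#'   forces are the exact negative gradient of the network energy with respect
#'   to the inputs. A committee of M independently initialised members
#'   provides query-by-committee uncertainty: the spread (population standard
#'   deviation) of member energies flags unreliable regions.
#'
#'   Training minimises `w_E * MSE(energy) + w_F * MSE(forces)` with
#'   full-batch Adam; both loss terms have analytic parameter gradients
#'   (the force term involves second derivatives of the network, derived in
#'   closed form for this architecture). Energy targets are standardised
#'   (shift/scale recomputed when data is ingested) so the output bias does
#'   not have to traverse large absolute energies.
#' @name surrogate
NULL

derive_seed <- function(seed, ...) {
  ids <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in ids) {
    s <- (s * 69069 + 1234567 + 97 * as.double(k)) %% 2147483647
  }
  as.integer(s)
}

#' Initialise one committee member
#'
#' @param input_dim Coordinate dimension D.
#' @param hidden_units Hidden-layer width.
#' @param seed Integer seed for the weight draw (members of a committee use
#'   distinct seeds derived from the run seed and their `model_id`).
#' @param model_id Identifier in `0..M-1`.
#' @return A `"qbc_model"` list: weight matrices `W1` (H x D), `b1`, `w2`,
#'   `b2`, energy standardisation `e_shift`/`e_scale`, and `version`.
#' @export
model_init <- function(input_dim, hidden_units = 24L, seed = 1L,
                       model_id = 0L) {
  old <- get0(".Random.seed", envir = .GlobalEnv)
  set.seed(derive_seed(seed, 1000L + model_id))
  H <- as.integer(hidden_units); D <- as.integer(input_dim)
  sd1 <- 1 / sqrt(D)
  m <- list(W1 = matrix(stats::rnorm(H * D, sd = sd1), H, D),
            b1 = stats::rnorm(H, sd = 0.3),
            w2 = stats::rnorm(H, sd = 1 / sqrt(H)),
            b2 = 0,
            e_shift = 0, e_scale = 1,
            H = H, D = D, model_id = as.integer(model_id),
            version = 0L)
  if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  structure(m, class = "qbc_model")
}

#' Batched energy and force inference
#'
#' Deterministic given the member's weights and inputs. Forces are the exact
#' negative input-gradient of the predicted energy.
#'
#' @param model A `"qbc_model"`.
#' @param X Coordinate batch, B x D matrix (a vector is treated as one row).
#' @return List with `energy` (length B) and `forces` (B x D matrix).
#' @export
model_predict <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  stopifnot(ncol(X) == model$D, nrow(X) >= 1L, all(is.finite(X)))
  Z <- X %*% t(model$W1)
  Z <- sweep(Z, 2L, model$b1, "+")
  Tm <- tanh(Z)
  e_std <- as.vector(Tm %*% model$w2) + model$b2
  S <- (1 - Tm^2) * rep(model$w2, each = nrow(X))
  G_std <- S %*% model$W1                     # d e_std / d x
  list(energy = e_std * model$e_scale + model$e_shift,
       forces = -G_std * model$e_scale)
}

# loss and parameter gradient on standardised targets.
# X: B x D, Et: standardised target energies (length B),
# Ft: B x D standardised target forces (already divided by e_scale),
# returns list(loss, grads) where grads has W1, b1, w2, b2.
model_loss_grad <- function(model, X, Et, Ft, w_energy = 1, w_force = 0.1) {
  B <- nrow(X); D <- model$D
  Z <- sweep(X %*% t(model$W1), 2L, model$b1, "+")
  Tm <- tanh(Z)
  S <- 1 - Tm^2
  e_hat <- as.vector(Tm %*% model$w2) + model$b2
  Sw <- S * rep(model$w2, each = B)
  G <- Sw %*% model$W1                        # predicted gradient; forces = -G
  Gt <- -Ft                                   # target gradient

  err_e <- e_hat - Et
  err_g <- G - Gt
  loss <- w_energy * mean(err_e^2) + w_force * mean(err_g^2)

  ce <- 2 * w_energy * err_e / B              # dL/de_hat
  gW1 <- (ce * S * rep(model$w2, each = B))
  grads <- list(
    W1 = t(gW1) %*% X,
    b1 = colSums(gW1),
    w2 = as.vector(t(Tm) %*% ce),
    b2 = sum(ce)
  )

  if (w_force > 0) {
    cg <- 2 * w_force * err_g / (B * D)       # dL/dG, B x D
    gW <- cg %*% t(model$W1)                  # B x H, row b: cg_b . W1[h,]
    grads$w2 <- grads$w2 + colSums(S * gW)
    grads$b1 <- grads$b1 - 2 * model$w2 * colSums(Tm * S * gW)
    grads$W1 <- grads$W1 +
      model$w2 * (t(S) %*% cg - 2 * t(Tm * S * gW) %*% X)
  }
  list(loss = loss, grads = grads)
}

adam_init <- function(model) {
  zero_like <- function(x) x * 0
  list(m = lapply(model[c("W1", "b1", "w2", "b2")], zero_like),
       v = lapply(model[c("W1", "b1", "w2", "b2")], zero_like),
       t = 0L)
}

adam_step <- function(model, grads, opt, lr = 0.02, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in c("W1", "b1", "w2", "b2")) {
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * grads[[nm]]
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    model[[nm]] <- model[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(model = model, opt = opt)
}

#' Flatten / restore a member's parameter block
#'
#' The flattened block is the fixed-shape payload of weight-synchronisation
#' messages and the unit of checkpointing.
#'
#' @param model A `"qbc_model"`.
#' @return `model_pack()` returns a numeric vector; `model_unpack()` returns
#'   the model with weights replaced from the vector.
#' @export
model_pack <- function(model) {
  c(as.vector(model$W1), model$b1, model$w2, model$b2,
    model$e_shift, model$e_scale)
}

#' @param block Numeric vector from [model_pack()].
#' @rdname model_pack
#' @export
model_unpack <- function(model, block) {
  H <- model$H; D <- model$D
  expected <- H * D + H + H + 1L + 2L
  if (length(block) != expected) {
    stop("parameter block length ", length(block),
         " does not match architecture (expected ", expected, ")")
  }
  model$W1 <- matrix(block[seq_len(H * D)], H, D)
  off <- H * D
  model$b1 <- block[off + seq_len(H)]; off <- off + H
  model$w2 <- block[off + seq_len(H)]; off <- off + H
  model$b2 <- block[off + 1L]
  model$e_shift <- block[off + 2L]
  model$e_scale <- block[off + 3L]
  model
}

#' Initialise a prediction-side committee
#'
#' @param cfg A validated [workflow_config()].
#' @return List of M `"qbc_model"` members with distinct initialisation
#'   seeds derived from `(cfg$seed, model_id)`.
#' @export
committee_init <- function(cfg) {
  cfg <- validate_config(cfg)
  lapply(seq_len(cfg$n_committee) - 1L, function(m) {
    model_init(cfg$input_dim, cfg$hidden_units, seed = cfg$seed, model_id = m)
  })
}

#' Batched committee inference
#'
#' @param committee List of `"qbc_model"` members.
#' @param X Coordinate batch, B x D.
#' @return List with `per_model_energy` (B x M), `per_model_forces`
#'   (list of M B x D matrices), `mean_energy`, `std_energy` (population,
#'   divide-by-M), `mean_forces` (B x D).
#' @export
committee_predict <- function(committee, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  M <- length(committee)
  preds <- lapply(committee, function(member) model_predict(member, X))
  E <- vapply(preds, `[[`, numeric(nrow(X)), "energy")
  E <- matrix(E, nrow = nrow(X), ncol = M)
  Fsum <- Reduce(`+`, lapply(preds, `[[`, "forces"))
  mean_E <- rowMeans(E)
  std_E <- sqrt(rowMeans((E - mean_E)^2))
  list(per_model_energy = E,
       per_model_forces = lapply(preds, `[[`, "forces"),
       mean_energy = mean_E,
       std_energy = std_E,
       mean_forces = Fsum / M)
}

#' Adopt trainer-exported weights into a prediction-side member
#'
#' Adoption is atomic per member and version-monotone: a block with a version
#' not greater than the member's current version is dropped (stale update)
#' and the member is returned unchanged.
#'
#' @param member Prediction-side `"qbc_model"`.
#' @param block Flattened parameter block from [model_pack()].
#' @param version Export version (the trainer's epoch counter).
#' @return List with `member` (possibly updated) and logical `adopted`.
#' @export
adopt_weights <- function(member, block, version) {
  if (version <= member$version) {
    return(list(member = member, adopted = FALSE))
  }
  member <- model_unpack(member, block)
  member$version <- as.integer(version)
  list(member = member, adopted = TRUE)
}
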