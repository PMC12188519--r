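#' @title Demo oracles: closed-form potentials with analytic gradients
#' @description In production active-learning workflows the oracle is a
#'   quantum-chemistry (or other high-fidelity) calculation. The demo stack
#'   ships two closed-form stand-ins with exact analytic gradients — the
#'   Mueller-Brown two-dimensional surface and Lennard-Jones N-particle
#'   clusters — plus a plug-in contract for user-supplied labelers.
#' @name oracles
NULL

#' Standard Mueller-Brown parameters
#'
#' The four-Gaussian parameter set in universal use for this test surface
#' (Mueller & Brown, Theor. Chim. Acta 53, 75 (1979)):
#' \eqn{V(x,y) = \sum_{i=1}^4 A_i \exp[a_i (x-x_i^0)^2 + b_i (x-x_i^0)(y-y_i^0)
#' + c_i (y-y_i^0)^2]}.
#'
#' @return A list with numeric vectors `A`, `a`, `b`, `c`, `x0`, `y0`, each of
#'   length 4.
#' @export
mb_standard_params <- function() {
  list(A = c(-200, -100, -170, 15),
       a = c(-1, -1, -6.5, 0.7),
       b = c(0, 0, 11, 0.6),
       c = c(-10, -10, -6.5, 0.7),
       x0 = c(1, 0, -0.5, -1),
       y0 = c(0, 0.5, 1.5, 1))
}

#' Mueller-Brown oracle
#'
#' @param params Parameter set as returned by [mb_standard_params()]; exactly
#'   four Gaussian terms are required.
#' @param latency Virtual-time cost per label (emulates an expensive oracle in
#'   scheduler tests); >= 0.
#' @return A `"qbc_oracle"` object with `dim = 2`.
#' @export
oracle_mueller_brown <- function(params = mb_standard_params(), latency = 0) {
  stopifnot(length(params$A) == 4L, length(params$a) == 4L,
            length(params$b) == 4L, length(params$c) == 4L,
            length(params$x0) == 4L, length(params$y0) == 4L)
  p <- params
  energy_fn <- function(coords) {
    dx <- coords[1L] - p$x0; dy <- coords[2L] - p$y0
    sum(p$A * exp(p$a * dx^2 + p$b * dx * dy + p$c * dy^2))
  }
  grad_fn <- function(coords) {
    dx <- coords[1L] - p$x0; dy <- coords[2L] - p$y0
    e <- p$A * exp(p$a * dx^2 + p$b * dx * dy + p$c * dy^2)
    c(sum(e * (2 * p$a * dx + p$b * dy)),
      sum(e * (p$b * dx + 2 * p$c * dy)))
  }
  structure(list(name = "mueller_brown", dim = 2L, params = p,
                 energy = energy_fn, gradient = grad_fn, latency = latency),
            class = "qbc_oracle")
}

#' Lennard-Jones cluster oracle
#'
#' Pairwise \eqn{4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]} over all unique
#' pairs of `n` particles with flattened 3N coordinates (atom-major x,y,z).
#' Pair distances below `0.3 * sigma` are numerically near-singular: the pair
#' force magnitude is clamped at its value at that separation and a warning is
#' recorded on the label.
#'
#' @param epsilon Well depth (reduced units), > 0.
#' @param sigma Length scale (reduced units), > 0.
#' @param n Particle count, >= 2.
#' @param latency Virtual-time cost per label.
#' @return A `"qbc_oracle"` object with `dim = 3 * n`.
#' @export
oracle_lennard_jones <- function(epsilon = 1, sigma = 1, n = 2L, latency = 0) {
  stopifnot(epsilon > 0, sigma > 0, n >= 2L)
  n <- as.integer(n)
  r_clamp <- 0.3 * sigma
  lj_pair <- function(r) 4 * epsilon * ((sigma / r)^12 - (sigma / r)^6)
  # dV/dr
  lj_dpair <- function(r) 4 * epsilon * (-12 * sigma^12 / r^13 + 6 * sigma^6 / r^7)
  eval_fn <- function(coords) {
    X <- matrix(coords, ncol = 3L, byrow = TRUE)
    E <- 0
    G <- matrix(0, nrow = n, ncol = 3L)
    clamped <- FALSE
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- X[i, ] - X[j, ]
        r <- sqrt(sum(d * d))
        if (r < r_clamp) {
          clamped <- TRUE
          E <- E + lj_pair(r_clamp)
          dp <- lj_dpair(r_clamp)
          r <- max(r, 1e-12)
        } else {
          E <- E + lj_pair(r)
          dp <- lj_dpair(r)
        }
        g <- dp * d / r
        G[i, ] <- G[i, ] + g
        G[j, ] <- G[j, ] - g
      }
    }
    list(energy = E, gradient = as.vector(t(G)), clamped = clamped)
  }
  structure(list(name = "lennard_jones", dim = 3L * n,
                 params = list(epsilon = epsilon, sigma = sigma, n = n),
                 energy = function(coords) eval_fn(coords)$energy,
                 gradient = function(coords) eval_fn(coords)$gradient,
                 eval = eval_fn, latency = latency),
            class = "qbc_oracle")
}

#' Wrap user-supplied energy/gradient functions as an oracle
#'
#' The plug-in contract production users implement: a function of a flattened
#' coordinate vector returning the energy, and one returning the gradient
#' (forces are its negation).
#'
#' @param energy_fn `function(coords) -> scalar energy`.
#' @param gradient_fn `function(coords) -> gradient vector` (same length as
#'   `coords`).
#' @param dim Coordinate dimension the functions expect.
#' @param name Identifier used in label provenance.
#' @param latency Virtual-time cost per label.
#' @return A `"qbc_oracle"` object.
#' @export
oracle_custom <- function(energy_fn, gradient_fn, dim, name = "custom",
                          latency = 0) {
  stopifnot(is.function(energy_fn), is.function(gradient_fn), dim >= 1)
  structure(list(name = name, dim = as.integer(dim), params = list(),
                 energy = energy_fn, gradient = gradient_fn,
                 latency = latency),
            class = "qbc_oracle")
}

#' @export
print.qbc_oracle <- function(x, ...) {
  cat(sprintf("<qbc_oracle '%s', dim=%d, latency=%g>\n",
              x$name, x$dim, x$latency))
  invisible(x)
}

#' Label a sample with ground truth
#'
#' Deterministic: identical coordinates produce the identical label whichever
#' oracle instance computes it.
#'
#' @param oracle A `"qbc_oracle"`.
#' @param coords Flattened coordinate vector of length `oracle$dim`.
#' @param provenance Identifier of the labeling oracle instance.
#' @return A labeled sample: list with `coords`, `energy`, `forces`
#'   (negative gradient), `provenance`, and logical `clamped`.
#' @export
oracle_label <- function(oracle, coords, provenance = oracle$name) {
  stopifnot(inherits(oracle, "qbc_oracle"))
  coords <- as.numeric(coords)
  if (length(coords) != oracle$dim) {
    stop("coordinate dimension ", length(coords),
         " does not match oracle dimension ", oracle$dim)
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates cannot be labeled")
  if (!is.null(oracle$eval)) {
    ev <- oracle$eval(coords)
    if (isTRUE(ev$clamped)) {
      warning("near-singular pair distance: forces clamped", call. = FALSE)
    }
    res <- list(coords = coords, energy = ev$energy,
                forces = -ev$gradient, provenance = provenance,
                clamped = isTRUE(ev$clamped))
  } else {
    res <- list(coords = coords, energy = oracle$energy(coords),
                forces = -oracle$gradient(coords), provenance = provenance,
                clamped = FALSE)
  }
  if (!is.finite(res$energy) || !all(is.finite(res$forces))) {
    stop("oracle produced a non-finite label")
  }
  res
}

#' Check analytic forces against central finite differences
#'
#' @param oracle A `"qbc_oracle"`.
#' @param point Coordinate vector at which to compare.
#' @param step Finite-difference step.
#' @return Maximum absolute deviation between the analytic gradient and the
#'   central finite-difference gradient.
#' @export
gradient_check <- function(oracle, point, step = 1e-6) {
  stopifnot(inherits(oracle, "qbc_oracle"), length(point) == oracle$dim)
  g <- oracle$gradient(point)
  fd <- vapply(seq_along(point), function(k) {
    hi <- point; hi[k] <- hi[k] + step
    lo <- point; lo[k] <- lo[k] - step
    (oracle$energy(hi) - oracle$energy(lo)) / (2 * step)
  }, numeric(1))
  max(abs(g - fd))
}

#' Locate the Mueller-Brown global minimum by grid search plus descent
#'
#' Dense grid scan over the standard viewing box, BFGS descent from the best
#' grid point, then Newton polish using the analytic Hessian so the gradient
#' norm reaches machine-level accuracy.
#'
#' @param oracle A Mueller-Brown oracle from [oracle_mueller_brown()].
#' @param grid_n Grid points per axis.
#' @param xlim,ylim Scan box.
#' @return List with `point` (length 2), `value`, `grad_norm`.
#' @export
mb_locate_minimum <- function(oracle = oracle_mueller_brown(), grid_n = 200L,
                              xlim = c(-1.5, 1.2), ylim = c(-0.2, 2.0)) {
  stopifnot(inherits(oracle, "qbc_oracle"), oracle$name == "mueller_brown")
  p <- oracle$params
  gx <- seq(xlim[1], xlim[2], length.out = grid_n)
  gy <- seq(ylim[1], ylim[2], length.out = grid_n)
  grid <- as.matrix(expand.grid(gx, gy))
  vals <- mb_energy_grid(oracle, grid)
  best <- unname(grid[which.min(vals), ])
  opt <- stats::optim(best, oracle$energy, oracle$gradient, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  pt <- opt$par
  hess <- function(q) {
    dx <- q[1] - p$x0; dy <- q[2] - p$y0
    e <- p$A * exp(p$a * dx^2 + p$b * dx * dy + p$c * dy^2)
    u <- 2 * p$a * dx + p$b * dy
    v <- p$b * dx + 2 * p$c * dy
    matrix(c(sum(e * (u^2 + 2 * p$a)), sum(e * (u * v + p$b)),
             sum(e * (u * v + p$b)), sum(e * (v^2 + 2 * p$c))), 2L, 2L)
  }
  for (i in 1:20) {
    g <- oracle$gradient(pt)
    if (sqrt(sum(g^2)) < 1e-12) break
    pt <- pt - solve(hess(pt), g)
  }
  list(point = pt, value = oracle$energy(pt),
       grad_norm = sqrt(sum(oracle$gradient(pt)^2)))
}

#' Vectorised Mueller-Brown energies over a matrix of points
#'
#' @param oracle A Mueller-Brown oracle.
#' @param X Matrix with two columns (x, y), one row per point.
#' @return Numeric vector of energies.
#' @export
mb_energy_grid <- function(oracle, X) {
  p <- oracle$params
  X <- as.matrix(X)
  stopifnot(ncol(X) == 2L)
  out <- numeric(nrow(X))
  for (i in 1:4) {
    dx <- X[, 1] - p$x0[i]; dy <- X[, 2] - p$y0[i]
    out <- out + p$A[i] * exp(p$a[i] * dx^2 + p$b[i] * dx * dy + p$c[i] * dy^2)
  }
  out
}
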