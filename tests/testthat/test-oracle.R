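test_that("the dimer pair potential has its textbook landmarks", {
  oracle <- oracle_lennard_jones(epsilon = 1, sigma = 1, n = 2L)
  # minimum at r = 2^(1/6): energy -epsilon, vanishing net force
  rmin <- 2^(1 / 6)
  lab <- oracle_label(oracle, c(0, 0, 0, rmin, 0, 0))
  expect_equal(lab$energy, -1, tolerance = 1e-12)
  expect_lt(max(abs(lab$forces)), 1e-10)
  # zero crossing at r = sigma
  lab0 <- oracle_label(oracle, c(0, 0, 0, 1, 0, 0))
  expect_equal(lab0$energy, 0, tolerance = 1e-12)
  # scaling with epsilon and sigma
  o2 <- oracle_lennard_jones(epsilon = 2.5, sigma = 1.3, n = 2L)
  lab2 <- oracle_label(o2, c(0, 0, 0, 1.3 * rmin, 0, 0))
  expect_equal(lab2$energy, -2.5, tolerance = 1e-12)
})

test_that("analytic gradients agree with central finite differences", {
  mb <- oracle_mueller_brown()
  set.seed(12)
  worst <- 0
  for (i in 1:100) {
    pt <- c(stats::runif(1, -1.5, 1.2), stats::runif(1, -0.2, 2))
    worst <- max(worst, gradient_check(mb, pt))
  }
  expect_lt(worst, 1e-5)

  lj3 <- oracle_lennard_jones(n = 3L)
  set.seed(13)
  worst <- 0
  for (i in 1:20) {
    pt <- as.vector(t(matrix(stats::rnorm(9, sd = 2), 3, 3) +
                        5 * diag(3)))  # well-separated trimer
    worst <- max(worst, gradient_check(lj3, pt))
  }
  expect_lt(worst, 1e-6)
})

test_that("the located Mueller-Brown minimum matches the pinned landmark", {
  # landmark pinned from a pre-build dense-grid + descent run:
  # (-0.558223634633024, 1.441725841804669), V = -146.699517209954
  loc <- mb_locate_minimum()
  expect_equal(loc$point, c(-0.558223634633024, 1.441725841804669),
               tolerance = 1e-9)
  expect_equal(loc$value, -146.699517209954, tolerance = 1e-10)
  expect_lt(loc$grad_norm, 1e-8)
})

test_that("rigid translations leave energy unchanged and forces sum to zero", {
  oracle <- oracle_lennard_jones(n = 4L)
  set.seed(21)
  X <- matrix(stats::rnorm(12, sd = 1.5), 4, 3) + 3 * diag(4)[, 1:3]
  coords <- as.vector(t(X))
  lab <- oracle_label(oracle, coords)
  shift <- rep(c(1.3, -0.7, 2.2), times = 4)
  lab_shift <- oracle_label(oracle, coords + shift)
  expect_equal(lab$energy, lab_shift$energy, tolerance = 1e-10)
  expect_equal(lab$forces, lab_shift$forces, tolerance = 1e-10)
  net <- colSums(matrix(lab$forces, ncol = 3, byrow = TRUE))
  expect_lt(max(abs(net)), 1e-10)
})

test_that("labeling is deterministic and validates dimensions", {
  oracle <- oracle_mueller_brown()
  a <- oracle_label(oracle, c(0.1, 0.5), provenance = "oracle/0")
  b <- oracle_label(oracle, c(0.1, 0.5), provenance = "oracle/3")
  expect_identical(a$energy, b$energy)
  expect_identical(a$forces, b$forces)
  expect_identical(a$provenance, "oracle/0")
  expect_error(oracle_label(oracle, c(1, 2, 3)), "dimension")
  expect_error(oracle_label(oracle, c(NaN, 0)), "non-finite")
})

test_that("near-singular pair distances are clamped with a warning", {
  oracle <- oracle_lennard_jones()
  expect_warning(lab <- oracle_label(oracle, c(0, 0, 0, 0.1, 0, 0)),
                 "clamped")
  expect_true(is.finite(lab$energy))
  expect_true(all(is.finite(lab$forces)))
  expect_true(lab$clamped)
})

test_that("user-supplied oracles plug into the same labeling contract", {
  bowl <- oracle_custom(function(x) sum(x^2), function(x) 2 * x, dim = 3L,
                        name = "bowl")
  lab <- oracle_label(bowl, c(1, 2, 2))
  expect_equal(lab$energy, 9)
  expect_equal(lab$forces, c(-2, -4, -4))
  expect_lt(gradient_check(bowl, c(0.3, -0.4, 1)), 1e-6)
})
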