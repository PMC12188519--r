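test_that("aggregation computes mean and population std over the model axis", {
  # identical outputs: zero spread
  agg <- aggregate_predictions(rep(3.7, 4), matrix(1, 4, 2))
  expect_equal(agg$mean_energy, 3.7)
  expect_equal(agg$std_energy, 0)

  # {1,2,3,4}: population std is sqrt(1.25)
  agg <- aggregate_predictions(c(1, 2, 3, 4), matrix(0, 4, 2))
  expect_equal(agg$mean_energy, 2.5)
  expect_equal(agg$std_energy, sqrt(1.25))

  # committee of four aggregates exactly four values
  agg <- aggregate_predictions(c(0.1, 0.2, 0.3, 0.4),
                               matrix(seq_len(12), 4, 3))
  expect_length(agg$mean_forces, 3L)
  expect_equal(agg$mean_forces, colMeans(matrix(seq_len(12), 4, 3)))
})

test_that("aggregation matches brute-force arithmetic on random committees", {
  set.seed(99)
  worst <- 0
  for (i in 1:200) {
    M <- sample(c(2L, 4L, 8L), 1)
    D <- sample(2:5, 1)
    e <- stats::rnorm(M, sd = 10)
    f <- matrix(stats::rnorm(M * D), M, D)
    agg <- aggregate_predictions(e, f)
    bf_mean <- sum(e) / M
    bf_std <- sqrt(sum((e - bf_mean)^2) / M)
    worst <- max(worst, abs(agg$mean_energy - bf_mean),
                 abs(agg$std_energy - bf_std))
  }
  expect_lt(worst, 1e-12)
})

test_that("non-finite member output marks the sample unreliable", {
  agg <- aggregate_predictions(c(1, NaN, 3, 4), matrix(0, 4, 2))
  expect_false(agg$finite_ok)
  expect_identical(agg$std_energy, Inf)
  verdict <- assess_reliability(agg, threshold = 100)
  expect_false(verdict$reliable)
  expect_true(verdict$label)
})

test_that("reliability follows strict 'exceeds' semantics at the boundary", {
  expect_true(assess_reliability(list(std_energy = 0), 0.1)$reliable)
  expect_false(assess_reliability(list(std_energy = 0), 0.1)$label)
  v <- assess_reliability(list(std_energy = 0.2), 0.1)
  expect_false(v$reliable)
  expect_true(v$label)
  # equality counts as reliable: forwarding requires std to exceed the bound
  v <- assess_reliability(list(std_energy = 0.1), 0.1)
  expect_true(v$reliable)
  expect_false(v$label)
})

test_that("a selection hook overrides labeling but never the reliability flag", {
  pred <- list(std_energy = 0.05)
  v <- assess_reliability(pred, 0.1, hook = function(p) TRUE)
  expect_true(v$reliable)
  expect_true(v$label)
  v <- assess_reliability(list(std_energy = 5), 0.1,
                          hook = function(p) FALSE)
  expect_false(v$reliable)
  expect_false(v$label)
  expect_error(assess_reliability(pred, 0.1, hook = function(p) stop("boom")),
               "boom")
  expect_error(assess_reliability(pred, 0.1, hook = function(p) NA),
               "TRUE/FALSE")
})

test_that("oracle dispatch is FIFO to the lowest-index idle oracle", {
  buf <- oracle_buffer_new(2L)
  for (i in 1:3) {
    buf <- oracle_buffer_enqueue(buf, list(sample_id = i,
                                           coords = c(i, i)))$buf
  }
  out <- dispatch_to_oracle(buf)
  expect_length(out$assignments, 2L)
  expect_identical(out$assignments[[1]]$sample$sample_id, 1L)
  expect_identical(out$assignments[[1]]$oracle_index, 1L)
  expect_identical(out$assignments[[2]]$sample$sample_id, 2L)
  expect_identical(out$assignments[[2]]$oracle_index, 2L)
  expect_length(out$buf$pending, 1L)

  # all oracles busy: nothing happens
  again <- dispatch_to_oracle(out$buf)
  expect_length(again$assignments, 0L)
  expect_length(again$buf$pending, 1L)

  # completing oracle 1 frees it for the remaining sample
  buf <- oracle_buffer_complete(out$buf, 1L, 1L)
  out2 <- dispatch_to_oracle(buf)
  expect_identical(out2$assignments[[1]]$sample$sample_id, 3L)
  expect_identical(out2$assignments[[1]]$oracle_index, 1L)
})

test_that("duplicate sample ids are ignored on enqueue", {
  buf <- oracle_buffer_new(1L)
  r1 <- oracle_buffer_enqueue(buf, list(sample_id = 5L, coords = c(0, 0)))
  expect_true(r1$accepted)
  r2 <- oracle_buffer_enqueue(r1$buf, list(sample_id = 5L, coords = c(1, 1)))
  expect_false(r2$accepted)
  expect_length(r2$buf$pending, 1L)
})

test_that("a label from an oracle not computing that sample is an error", {
  buf <- oracle_buffer_new(1L)
  buf <- oracle_buffer_enqueue(buf, list(sample_id = 1L, coords = c(0, 0)))$buf
  buf <- dispatch_to_oracle(buf)$buf
  expect_error(oracle_buffer_complete(buf, 1L, 99L), "not computing")
})

test_that("the training buffer flushes exactly at its threshold", {
  buf <- training_buffer_new(3L)
  out <- collect_label(buf, list(energy = 1))
  expect_false(out$flush_due)
  out <- collect_label(out$buf, list(energy = 2))
  expect_false(out$flush_due)
  out <- collect_label(out$buf, list(energy = 3))
  expect_true(out$flush_due)

  fl <- flush_training_buffer(out$buf)
  expect_length(fl$batch, 3L)
  expect_length(fl$buf$items, 0L)

  # threshold 1 flushes on every label
  b1 <- training_buffer_new(1L)
  expect_true(collect_label(b1, list(energy = 0))$flush_due)

  expect_error(flush_training_buffer(training_buffer_new(5L)),
               "below threshold")
})

test_that("a buffer-adjust hook controls what survives a flush", {
  buf <- training_buffer_new(4L)
  for (i in 1:4) buf <- collect_label(buf, list(energy = i))$buf
  fl <- flush_training_buffer(buf, hook = function(items) {
    items[3:4]  # keep the newest two
  })
  expect_length(fl$batch, 4L)
  expect_length(fl$buf$items, 2L)
  expect_equal(fl$buf$items[[1]]$energy, 3)
})
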