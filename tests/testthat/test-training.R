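test_that("cross-entropy loss matches closed forms, with the L2 penalty added", {
  expect_equal(computeLoss(c(0, 1), "match"), 0)
  expect_equal(computeLoss(c(0.5, 0.5), "match"), log(2))
  expect_equal(computeLoss(c(0.5, 0.5), 0), log(2))
  # a single weight w = 2 with coefficient 1e-3 adds 1e-3 * 4
  expect_equal(computeLoss(c(0, 1), 1, weights = list(w = 2), l2 = 1e-3),
               0.004)
  # clamping keeps the loss finite at p = 0
  expect_true(is.finite(computeLoss(c(1, 0), "match")))
  expect_error(computeLoss(c(0.5, 0.5), "maybe"), class = "phn_contract_error")
})

test_that("gradient clipping rescales by the global norm only above threshold", {
  g <- list(a = c(3, 0), b = matrix(0, 2, 2))     # norm 3: untouched
  expect_equal(clipGradients(g, 5)$a, c(3, 0))
  g2 <- list(a = c(6, 0), b = c(0, 8))            # norm 10 -> scaled to 5
  out <- clipGradients(g2, 5)
  expect_equal(attr(out, "global_norm"), 10)
  expect_equal(sqrt(sum(unlist(out)^2)), 5, tolerance = 1e-6)
  expect_equal(out$a, c(3, 0), tolerance = 1e-6)  # proportional rescale
  z <- list(a = c(0, 0))
  expect_equal(clipGradients(z, 5)$a, c(0, 0))    # identity at the origin
  expect_error(clipGradients(list(a = c(1, NaN))), class = "phn_data_error")
  expect_error(clipGradients(list(a = c(1, Inf))), class = "phn_data_error")
})

test_that("post-clip norms stay bounded on synthetic exploding gradients", {
  set.seed(33)
  for (i in 1:10) {
    g <- lapply(1:4, function(j) matrix(rnorm(20, sd = 10^i), 4, 5))
    out <- clipGradients(g, 5)
    expect_lte(sqrt(sum(unlist(out)^2)), 5 + 1e-6)
  }
})

test_that("batch-norm moving statistics follow the exponential moving average", {
  u <- updateBnStatistics(1, 1, 0, 0)
  expect_equal(u$mean, 0.001)
  expect_equal(updateBnStatistics(3, 2, 3, 2)$mean, 3)  # fixed point
  # geometric series: after n identical batches with value v from 0,
  # moving = v * (1 - 0.999^n)
  v <- 2.5
  mm <- 0
  for (i in 1:50) mm <- updateBnStatistics(v, v, mm, mm)$mean
  expect_equal(mm, v * (1 - 0.999^50), tolerance = 1e-9)
})

test_that("training runs, records finite history and is seed-reproducible", {
  ds <- smallDataset(seed = 3)
  seqs <- as.character(genomeSequences(ds))
  pairs <- as.data.frame(interactionPairs(ds))
  tab <- trainSkipgram(seqs, dim = 8, epochs = 1, seed = 2)
  cfg <- reducedModelConfig()
  tc <- trainConfig(epochs = 2, learning_rate = 1e-3, batch_size = 8,
                    l2_coefficient = 1e-4, seed = 5, recalibrate = FALSE)
  f1 <- trainModel(initModel(cfg, seed = 4), pairs, seqs, tab, tc)
  expect_equal(nrow(f1$history), 2L)
  expect_true(all(is.finite(f1$history$loss)))
  expect_true(all(f1$history$grad_norm_max <= 5 + 1e-6))
  f2 <- trainModel(initModel(cfg, seed = 4), pairs, seqs, tab, tc)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$model@params[["mlp.W2"]], f2$model@params[["mlp.W2"]])
})

test_that("unresolvable pair ids fail before training starts", {
  ds <- smallDataset(seed = 3)
  seqs <- as.character(genomeSequences(ds))
  pairs <- as.data.frame(interactionPairs(ds))
  pairs$host_id[1] <- "missing_host"
  tab <- randomEmbedding(3, 8, seed = 1)
  expect_error(trainModel(initModel(reducedModelConfig(), 1), pairs, seqs,
                          tab, trainConfig(epochs = 1)),
               class = "phn_data_error")
})

test_that("the L2 term shrinks weights relative to unregularized training", {
  ds <- smallDataset(seed = 9)
  seqs <- as.character(genomeSequences(ds))
  pairs <- as.data.frame(interactionPairs(ds))
  tab <- trainSkipgram(seqs, dim = 8, epochs = 1, seed = 2)
  cfg <- reducedModelConfig()
  norms <- sapply(c(0, 0.05), function(l2) {
    tc <- trainConfig(epochs = 3, learning_rate = 1e-3, batch_size = 8,
                      l2_coefficient = l2, seed = 5, recalibrate = FALSE)
    fit <- trainModel(initModel(cfg, seed = 4), pairs, seqs, tab, tc)
    sum(fit$model@params[["mlp.W1"]]^2)
  })
  expect_lt(norms[2], norms[1])
})

test_that("training accepts a dataset object directly and a validation split", {
  ds <- smallDataset(seed = 12)
  tab <- trainSkipgram(as.character(genomeSequences(ds)), dim = 8,
                       epochs = 1, seed = 2)
  tc <- trainConfig(epochs = 1, learning_rate = 1e-3, batch_size = 4,
                    seed = 3, recalibrate = FALSE)
  fit <- trainModel(initModel(reducedModelConfig(), 1), ds, table = tab,
                    config = tc)
  expect_s4_class(fit$model, "SiameseHostModel")
  expect_equal(nrow(fit$history), 1L)
})
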