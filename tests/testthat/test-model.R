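test_that("model configuration enforces the architectural constraints", {
  cfg <- modelConfig()
  expect_equal(cfg$n_heads * cfg$head_dim, cfg$tower_dim)
  expect_equal(cfg$conv_channels[3], cfg$tower_dim)
  expect_error(modelConfig(n_heads = 3), class = "phn_config_error")
  expect_error(modelConfig(conv_channels = c(64, 128)), class = "phn_config_error")
  expect_error(modelConfig(conv_channels = c(64, 128, 200)),
               class = "phn_config_error")
  expect_error(modelConfig(conv_kernel = 4), class = "phn_config_error")
})

test_that("scaled dot-product attention matches an explicit-loop oracle", {
  set.seed(42)
  for (rep in 1:5) {
    Q <- matrix(rnorm(3 * 64), 3, 64)
    K <- matrix(rnorm(3 * 64), 3, 64)
    V <- matrix(rnorm(3 * 64), 3, 64)
    out <- attentionHead(Q, K, V, d_k = 64)
    expect_lt(max(abs(out - loopAttention(Q, K, V, 64))), 1e-5)
    W <- attr(out, "weights")
    expect_equal(rowSums(W), rep(1, 3), tolerance = 1e-12)
    expect_true(all(W >= 0))
  }
  # single-position sequence: the output is the value row itself
  q <- matrix(rnorm(8), 1)
  out1 <- attentionHead(q, q, q, d_k = 8)
  expect_equal(as.vector(out1), as.vector(q), tolerance = 1e-12)
  expect_error(attentionHead(q, q, q, d_k = -1), class = "phn_config_error")
})

test_that("tiny end-to-end forward yields a probability simplex, deterministically", {
  m <- initModel(tinyModelConfig(), seed = 3)
  tab <- randomEmbedding(3, 4, seed = 5)
  p1 <- forwardPair(m, randomDna(120, 1), randomDna(70, 2), tab)
  expect_named(p1, c("p_non_match", "p_match"))
  expect_true(all(p1 >= 0))
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  p2 <- forwardPair(m, randomDna(120, 1), randomDna(70, 2), tab)
  expect_identical(p1, p2)
})

test_that("towers have independent parameters: swapping inputs changes the output", {
  m <- initModel(tinyModelConfig(), seed = 11)
  tab <- randomEmbedding(3, 4, seed = 5)
  a <- randomDna(120, 21); b <- randomDna(120, 22)
  pab <- forwardPair(m, a, b, tab)
  pba <- forwardPair(m, b, a, tab)
  expect_false(isTRUE(all.equal(pab, pba, tolerance = 1e-8)))
})

test_that("the CNN tower maps any segment extent to a fixed-length vector", {
  cfgA <- tinyModelConfig()
  m <- initModel(cfgA, seed = 7)
  tab <- randomEmbedding(3, 4, seed = 5)
  X1 <- embedSegment(tokenizeKmers(randomDna(50, 1), expected_length = 50), tab)
  X2 <- embedSegment(tokenizeKmers(randomDna(30, 2), expected_length = 30), tab)
  v1 <- cnnTowerForward(X1, "phage", m)
  v2 <- cnnTowerForward(X2, "phage", m)
  expect_length(v1, 4L)
  expect_length(v2, 4L)
  expect_error(cnnTowerForward(X1[, 1:2], "phage", m),
               class = "phn_contract_error")
})

test_that("transformer encoding validates its inputs", {
  m <- initModel(tinyModelConfig(), seed = 2)
  seg <- matrix(rnorm(3 * 4), 3, 4)
  out <- transformerEncode(seg, model = m)
  expect_length(out, 4L)
  expect_error(transformerEncode(seg[0, , drop = FALSE], model = m),
               class = "phn_contract_error")
  expect_error(transformerEncode(seg, mask = c(FALSE, FALSE, FALSE), model = m),
               class = "phn_contract_error")
  expect_error(transformerEncode(seg, mask = c(TRUE, TRUE), model = m),
               class = "phn_contract_error")
})

test_that("segment count follows ceil(N/2000) through the pair forward", {
  m <- initModel(tinyModelConfig(segment_length = 2000L, d_embed = 8L,
                                 conv_channels = c(2L, 3L, 4L)), seed = 4)
  tab <- randomEmbedding(3, 8, seed = 5)
  # 4001 bp -> 3 segments; exercised through the full pipeline
  p <- forwardPair(m, randomDna(4001, 31), randomDna(2000, 32), tab)
  expect_equal(sum(p), 1, tolerance = 1e-6)
})

test_that("classifier head has the documented parameter count", {
  m <- initModel(modelConfig(), seed = 1)
  P <- modelParameters(m)
  headParams <- length(P[["mlp.W1"]]) + length(P[["mlp.b1"]]) +
    length(P[["mlp.W2"]]) + length(P[["mlp.b2"]])
  expect_identical(headParams, 512L * 4096L + 4096L + 4096L * 2L + 2L)
  expect_equal(dim(P[["mlp.W1"]]), c(512L, 4096L))
})

test_that("shared-tower variant reuses one parameter set for both towers", {
  m <- initModel(tinyModelConfig(share_tower_weights = TRUE), seed = 9)
  expect_true(any(grepl("^cnn\\.shared\\.", names(modelParameters(m)))))
  expect_false(any(grepl("^cnn\\.phage\\.", names(modelParameters(m)))))
  tab <- randomEmbedding(3, 4, seed = 5)
  a <- randomDna(100, 41)
  p <- forwardPair(m, a, a, tab)
  expect_equal(sum(p), 1, tolerance = 1e-6)
})
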