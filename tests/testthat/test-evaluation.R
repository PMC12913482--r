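test_that("hierarchical accuracy handles the identity and mixed hand-worked cases", {
  hl <- data.frame(host_id = c("h1", "h2", "h3", "h4"),
                   genus = c("g1", "g2", "g3", "g4"),
                   family = c("f1", "f1", "f3", "f4"),
                   order = c("o1", "o1", "o3", "o4"),
                   class = c("c1", "c1", "c3", "c4"),
                   phylum = c("P1", "P1", "P1", "P4"))
  truth <- data.frame(phage_id = paste0("p", 1:4), hl[c(1, 1, 3, 4), -1])
  # all four predicted correctly -> 1.0 everywhere
  predOK <- data.frame(phage_id = paste0("p", 1:4),
                       predicted_host_id = c("h1", "h1", "h3", "h4"))
  expect_equal(unname(rankAccuracies(hierarchicalAccuracy(predOK, truth, hl))),
               rep(1, 5))
  # p1 right at genus; p2 right only from family up (h2 shares f1/o1/c1/P1
  # with truth h1); p3 right only at phylum (h1 vs truth h3); p4 wrong at
  # every rank (h3 is in P1, truth h4 in P4)
  pred <- data.frame(phage_id = paste0("p", 1:4),
                     predicted_host_id = c("h1", "h2", "h1", "h3"))
  acc <- rankAccuracies(hierarchicalAccuracy(pred, truth, hl))
  expect_equal(unname(acc), c(0.25, 0.50, 0.50, 0.50, 0.75))
  rep <- hierarchicalAccuracy(pred, truth, hl)
  expect_equal(nScored(rep), 4L)
})

test_that("missing lineages raise data errors naming the offender", {
  hl <- data.frame(host_id = "h1", genus = "g", family = "f", order = "o",
                   class = "c", phylum = "P")
  truth <- data.frame(phage_id = "p1", genus = "g", family = "f",
                      order = "o", class = "c", phylum = "P")
  bad <- data.frame(phage_id = "p1", predicted_host_id = "hX")
  expect_error(hierarchicalAccuracy(bad, truth, hl), "hX",
               class = "phn_data_error")
  bad2 <- data.frame(phage_id = "pX", predicted_host_id = "h1")
  expect_error(hierarchicalAccuracy(bad2, truth, hl), "pX",
               class = "phn_data_error")
})

test_that("host ranking is sorted, tie-broken lexicographically, cache-consistent", {
  m <- initModel(tinyModelConfig(), seed = 6)
  tab <- randomEmbedding(3, 4, seed = 2)
  phage <- randomDna(150, 1)
  cands <- sapply(1:5, function(i) randomDna(100, 10 + i))
  names(cands) <- paste0("h", 5:1)  # unordered names on purpose
  rk <- rankHosts(m, phage, cands, tab)
  expect_equal(nrow(rk), 5L)
  expect_true(all(diff(rk$p_match) <= 0))
  expect_identical(attr(rk, "predicted_host_id"), rk$host_id[1])
  # cached candidate vectors agree with independent single-pair passes
  for (i in seq_len(5)) {
    p <- forwardPair(m, phage, cands[[rk$host_id[i]]], tab)
    expect_equal(rk$p_match[i], unname(p[["p_match"]]), tolerance = 1e-6)
  }
  # singleton candidate is predicted trivially
  one <- rankHosts(m, phage, cands[1], tab)
  expect_identical(attr(one, "predicted_host_id"), names(cands)[1])
  expect_error(rankHosts(m, phage, character(0), tab),
               class = "phn_contract_error")
})

test_that("test-set evaluation enforces train/test disjointness and n_total", {
  m <- initModel(tinyModelConfig(), seed = 8)
  tab <- randomEmbedding(3, 4, seed = 2)
  ds <- smallDataset(seed = 4, host_length = 200, phage_length = 200)
  seqs <- as.character(genomeSequences(ds))
  meta <- as.data.frame(genomeMeta(ds))
  phages <- seqs[meta$id[meta$role == "phage"]]
  hosts <- seqs[meta$id[meta$role == "host"]]
  expect_error(evaluateTestSet(m, phages, hosts, phageTruth(ds),
                               hostLineages(ds), tab,
                               train_phage_ids = names(phages)[1]),
               class = "phn_protocol_error")
  ev <- evaluateTestSet(m, phages, hosts, phageTruth(ds), hostLineages(ds),
                        tab)
  expect_equal(nScored(ev$report), length(phages))
  expect_equal(nrow(ev$rankings), length(phages) * length(hosts))
  # determinism of repeated evaluation
  ev2 <- evaluateTestSet(m, phages, hosts, phageTruth(ds), hostLineages(ds),
                         tab)
  expect_identical(ev$rankings$p_match, ev2$rankings$p_match)
})

test_that("an untrained model scores near the chance level implied by clade sizes", {
  m <- initModel(tinyModelConfig(), seed = 19)
  tab <- randomEmbedding(3, 4, seed = 2)
  ds <- simulateDataset(syntheticConfig(n_phyla = 4, hosts_per_genus = 2,
                                        phages_per_host = 3,
                                        host_length = 300,
                                        phage_length = 300, seed = 9))
  seqs <- as.character(genomeSequences(ds))
  meta <- as.data.frame(genomeMeta(ds))
  phages <- seqs[meta$id[meta$role == "phage"]]
  hosts <- seqs[meta$id[meta$role == "host"]]
  ev <- evaluateTestSet(m, phages, hosts, phageTruth(ds), hostLineages(ds), tab)
  # 4 balanced phyla: phylum-level chance is 0.25; even a degenerate
  # constant predictor stays below 0.75 with 24 phages (P < 1e-5)
  expect_lte(rankAccuracies(ev$report)[["phylum"]], 0.75)
})

test_that("binary pair accuracy resolves ids and counts argmax agreement", {
  m <- initModel(tinyModelConfig(), seed = 3)
  tab <- randomEmbedding(3, 4, seed = 2)
  ds <- smallDataset(seed = 5, host_length = 200, phage_length = 200)
  seqs <- as.character(genomeSequences(ds))
  pairs <- as.data.frame(interactionPairs(ds))
  out <- binaryPairAccuracy(m, pairs, seqs, tab)
  expect_equal(out$n, nrow(pairs))
  expect_true(out$accuracy >= 0 && out$accuracy <= 1)
  expect_length(out$p_match, nrow(pairs))
  pairs$phage_id[1] <- "nope"
  expect_error(binaryPairAccuracy(m, pairs, seqs, tab),
               class = "phn_data_error")
})
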