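# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no data files.

# A miniature architecture for fast structural tests (tower dim 4).
tinyModelConfig <- function(...) {
  args <- list(segment_length = 50L, k = 3L, d_embed = 4L, tower_dim = 4L,
               n_transformer_layers = 2L, n_heads = 2L, head_dim = 2L,
               ffn_dim = 8L, mlp_hidden = 8L, conv_channels = c(2L, 3L, 4L),
               pool_kernel = 2L)
  do.call(modelConfig, utils::modifyList(args, list(...)))
}

randomDna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small simulated dataset: 2 phyla x 2 hosts, one phage per host, 4 kb.
smallDataset <- function(seed = 1, ...) {
  simulateDataset(do.call(syntheticConfig, utils::modifyList(
    list(n_phyla = 2L, hosts_per_genus = 2L, phages_per_host = 1L,
         host_length = 4000L, phage_length = 4000L, seed = seed),
    list(...))))
}

# Explicit-loop scaled dot-product attention (independent of the vectorized
# implementation under test).
loopAttention <- function(Q, K, V, d_k) {
  n <- nrow(Q); m <- nrow(K)
  out <- matrix(0, n, ncol(V))
  for (i in seq_len(n)) {
    logits <- numeric(m)
    for (j in seq_len(m)) {
      s <- 0
      for (t in seq_len(ncol(Q))) s <- s + Q[i, t] * K[j, t]
      logits[j] <- s / sqrt(d_k)
    }
    w <- exp(logits - max(logits))
    w <- w / sum(w)
    for (j in seq_len(m))
      for (t in seq_len(ncol(V))) out[i, t] <- out[i, t] + w[j] * V[j, t]
  }
  out
}

# Brute-force double-loop hierarchical accuracy oracle.
bruteHierarchicalAccuracy <- function(predictions, truth, hostLin) {
  ranks <- c("genus", "family", "order", "class", "phylum")
  counts <- setNames(numeric(5), ranks)
  for (i in seq_len(nrow(predictions))) {
    ti <- which(truth$phage_id == predictions$phage_id[i])
    hi <- which(hostLin$host_id == predictions$predicted_host_id[i])
    for (r in ranks)
      if (truth[[r]][ti] == hostLin[[r]][hi])
        counts[r] <- counts[r] + 1
  }
  counts / nrow(predictions)
}

# Random tree-consistent lineage tables for evaluator tests.
randomLineages <- function(nHosts, nPhyla = 2, childrenPerRank = 2,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phyla <- paste0("P", seq_len(nPhyla))
  lin <- data.frame(host_id = paste0("h", seq_len(nHosts)))
  phylum <- sample(phyla, nHosts, replace = TRUE)
  cls <- paste0(phylum, ".c", sample(childrenPerRank, nHosts, TRUE))
  ord <- paste0(cls, ".o", sample(childrenPerRank, nHosts, TRUE))
  fam <- paste0(ord, ".f", sample(childrenPerRank, nHosts, TRUE))
  gen <- paste0(fam, ".g", sample(childrenPerRank, nHosts, TRUE))
  cbind(lin, genus = gen, family = fam, order = ord, class = cls,
        phylum = phylum)
}
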