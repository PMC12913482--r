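test_that("taxonomy generation yields the expected tree shape", {
  t1 <- generateTaxonomy(syntheticConfig(n_phyla = 2, children_per_node = 1))
  expect_equal(nrow(t1), 2L)
  for (r in c("genus", "family", "order", "class", "phylum"))
    expect_length(unique(t1[[r]]), 2L)
  t2 <- generateTaxonomy(syntheticConfig(n_phyla = 1, children_per_node = 2))
  expect_equal(nrow(t2), 16L)  # 2^4 genera under one phylum
  expect_length(unique(t2$phylum), 1L)
  expect_length(unique(t2$genus), 16L)
  # determinism
  expect_identical(t2, generateTaxonomy(syntheticConfig(n_phyla = 1,
                                                        children_per_node = 2)))
})

test_that("taxonomies are tree-consistent (no rank crossing)", {
  tax <- generateTaxonomy(syntheticConfig(n_phyla = 3, children_per_node = 2))
  parent <- c(genus = "family", family = "order", order = "class",
              class = "phylum")
  for (r in names(parent))
    expect_true(all(tapply(tax[[parent[[r]]]], tax[[r]],
                           function(z) length(unique(z))) == 1L))
})

test_that("clade profiles are probability vectors that decay in similarity down ranks", {
  cfg <- syntheticConfig(n_phyla = 2, children_per_node = 2, seed = 4)
  tax <- generateTaxonomy(cfg)
  prof <- generateCladeProfiles(tax, cfg)
  for (p in prof) {
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-9)
  }
  # a genus profile correlates more with its own phylum than a foreign one
  cors <- cor(prof[[tax$genus[1]]], prof[[tax$phylum[1]]])
  corf <- cor(prof[[tax$genus[1]]], prof[[tax$phylum[nrow(tax)]]])
  expect_gt(cors, corf)
})

test_that("host genomes follow their clade profile", {
  cfg <- syntheticConfig(host_length = 2000, seed = 3)
  tax <- generateTaxonomy(cfg)
  prof <- generateCladeProfiles(tax, cfg)
  set.seed(11)
  h <- generateHostGenome(tax[1, ], prof, cfg, "h1")
  expect_equal(nchar(h$sequence), 2000L)
  expect_true(all(strsplit(h$sequence, "")[[1]] %in% c("A", "C", "G", "T")))
  # degenerate profile concentrated on AAA emits an all-A genome
  degen <- prof
  degen[[tax$genus[1]]] <- c(1, rep(0, 63))
  hA <- generateHostGenome(tax[1, ], degen, cfg, "hA")
  expect_identical(hA$sequence, strrep("A", 2000))
  # empirical 3-mer frequencies of a 100 kb genome track the profile
  cfgBig <- syntheticConfig(host_length = 100000, seed = 3)
  hb <- generateHostGenome(tax[1, ], prof, cfgBig, "hb")
  r <- cor(kmerFrequencies(hb$sequence), prof[[tax$genus[1]]])
  expect_gt(r, 0.9)
  expect_error(generateHostGenome(data.frame(genus = "nope", family = "f",
                                             order = "o", class = "c",
                                             phylum = "p"), prof, cfg, "x"),
               class = "phn_data_error")
})

test_that("phage mimicry interpolates between uniform background and the host profile", {
  cfg0 <- syntheticConfig(phage_length = 50000, mimicry_strength = 0,
                          seed = 8)
  tax <- generateTaxonomy(cfg0)
  prof <- generateCladeProfiles(tax, cfg0)
  set.seed(21)
  host <- generateHostGenome(tax[1, ], prof, cfg0, "h")
  ph0 <- generatePhageGenome(host, prof, cfg0, "p0")
  expect_equal(nchar(ph0$sequence), 50000L)
  expect_identical(ph0$true_host_id, "h")
  # mimicry 0: non-overlapping 3-mer counts are multinomial-uniform
  bases <- strsplit(ph0$sequence, "")[[1]]
  starts <- seq(1, 50000 - 2, by = 3)
  triplets <- paste0(bases[starts], bases[starts + 1], bases[starts + 2])
  counts <- table(factor(triplets, levels = buildVocabulary(3)[1:64]))
  pval <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(pval, 0.01)
  # mimicry 1: composition matches the host clade profile
  cfg1 <- syntheticConfig(phage_length = 50000, mimicry_strength = 1, seed = 8)
  ph1 <- generatePhageGenome(host, prof, cfg1, "p1")
  expect_gt(cor(kmerFrequencies(ph1$sequence), prof[[tax$genus[1]]]), 0.9)
})

test_that("pair construction mirrors positives with phylum-exclusion negatives", {
  hosts <- data.frame(id = paste0("h", 1:6),
                      phylum = rep(c("PA", "PB", "PC"), each = 2))
  phages <- data.frame(id = paste0("p", seq_len(826)),
                       true_host_id = sample(hosts$id, 826, replace = TRUE))
  pairs <- buildPairDataset(phages, hosts, negatives_per_positive = 1,
                            seed = 5)
  expect_equal(sum(pairs$label == 1), 826L)
  expect_equal(sum(pairs$label == 0), 826L)
  expect_false(anyDuplicated(paste(pairs$phage_id, pairs$host_id)) > 0)
  # every negative host lies in a different phylum from the true host
  neg <- pairs[pairs$label == 0, ]
  truePhy <- hosts$phylum[match(phages$true_host_id[match(neg$phage_id, phages$id)],
                                hosts$id)]
  negPhy <- hosts$phylum[match(neg$host_id, hosts$id)]
  expect_true(all(negPhy != truePhy))
  # determinism
  expect_identical(pairs, buildPairDataset(phages, hosts, 1, seed = 5))
  expect_false(identical(pairs, buildPairDataset(phages, hosts, 1, seed = 6)))
})

test_that("single-phylum host sets make phylum exclusion infeasible", {
  hosts <- data.frame(id = c("h1", "h2"), phylum = c("PA", "PA"))
  phages <- data.frame(id = "p1", true_host_id = "h1")
  expect_error(buildPairDataset(phages, hosts), class = "phn_data_error")
})

test_that("simulated datasets are valid, deterministic objects", {
  ds <- smallDataset(seed = 2)
  expect_true(methods::validObject(ds))
  expect_identical(as.character(genomeSequences(ds)),
                   as.character(genomeSequences(smallDataset(seed = 2))))
  m <- as.data.frame(genomeMeta(ds))
  expect_equal(sum(m$role == "host"), 4L)
  expect_equal(sum(m$role == "phage"), 4L)
  expect_equal(nrow(interactionPairs(ds)), 8L)
})

test_that("the planted signal is recoverable by the composition baseline", {
  # mimicry 0.7 at 50 kb: the cosine nearest-profile baseline must place
  # most phages in the right phylum before any network training is trusted
  ds <- simulateDataset(syntheticConfig(n_phyla = 4, hosts_per_genus = 1,
                                        phages_per_host = 5,
                                        host_length = 50000,
                                        phage_length = 50000,
                                        mimicry_strength = 0.7, seed = 31))
  m <- as.data.frame(genomeMeta(ds))
  seqs <- as.character(genomeSequences(ds))
  pred <- nearestCompositionHost(seqs[m$id[m$role == "phage"]],
                                 seqs[m$id[m$role == "host"]])
  hl <- hostLineages(ds)
  tr <- phageTruth(ds)
  acc <- mean(hl$phylum[match(pred, hl$host_id)] ==
              tr$phylum[match(names(pred), tr$phage_id)])
  expect_gt(acc, 0.8)
})
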