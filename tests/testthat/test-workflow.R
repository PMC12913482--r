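wfConfig <- function(dir, ...) {
  utils::modifyList(list(
    seed = 5,
    output_dir = dir,
    synthetic = list(n_phyla = 2, hosts_per_genus = 1, phages_per_host = 1,
                     host_length = 4000, phage_length = 4000),
    split = list(test_fraction = 0.5),
    embedding = list(epochs = 1),
    model = list(reduced = TRUE),
    training = list(epochs = 1, learning_rate = 1e-3, batch_size = 2,
                    l2_coefficient = 1e-4)), list(...))
}

test_that("stage seeds are deterministic, distinct, 32-bit positive integers", {
  s1 <- stageSeed(42, "train")
  expect_identical(s1, stageSeed(42, "train"))
  expect_false(s1 == stageSeed(42, "embed"))
  expect_false(s1 == stageSeed(43, "train"))
  expect_true(s1 > 0 && s1 < 2^31)
  expect_type(s1, "integer")
})

test_that("simulate stage materializes a complete, reproducible dataset directory", {
  dir <- file.path(tempdir(), "wf-sim")
  unlink(dir, recursive = TRUE)
  cfg <- wfConfig(dir)
  out <- runSimulate(cfg)
  files <- c("hosts.fasta", "phages.fasta", "host_lineages.tsv", "pairs.tsv",
             "manifest.json")
  expect_true(all(file.exists(file.path(out, files))))
  pairs <- read.delim(file.path(out, "pairs.tsv"))
  expect_equal(sum(pairs$label == 1), 2L)   # 2 phages
  expect_equal(sum(pairs$label == 0), 2L)
  md5a <- tools::md5sum(file.path(out, files[1:4]))
  # rerun: byte-identical outputs
  runSimulate(cfg)
  expect_identical(unname(md5a),
                   unname(tools::md5sum(file.path(out, files[1:4]))))
  # manifest verification detects tampering
  expect_silent(verifyManifest(out))
  cat("X", file = file.path(out, "pairs.tsv"), append = TRUE)
  expect_error(verifyManifest(out), class = "phn_data_error")
})

test_that("a single-phylum config propagates the exclusion error", {
  dir <- file.path(tempdir(), "wf-onephy")
  cfg <- wfConfig(dir, synthetic = list(n_phyla = 1, hosts_per_genus = 1,
                                        phages_per_host = 1,
                                        host_length = 3000,
                                        phage_length = 3000))
  expect_error(runSimulate(cfg), class = "phn_data_error")
})

test_that("datasets round-trip through the on-disk format", {
  dir <- file.path(tempdir(), "wf-rt")
  unlink(dir, recursive = TRUE)
  cfg <- wfConfig(dir)
  runSimulate(cfg)
  ds <- loadDatasetDir(file.path(dir, "dataset"))
  expect_s4_class(ds, "PhageHostDataSet")
  m <- as.data.frame(genomeMeta(ds))
  expect_equal(sum(m$role == "host"), 2L)
  expect_equal(sum(m$role == "phage"), 2L)
  expect_true(all(nchar(as.character(genomeSequences(ds))) == 4000L))
})

test_that("embed/train/evaluate stages compose into a reproducible run", {
  dir <- file.path(tempdir(), "wf-full")
  unlink(dir, recursive = TRUE)
  cfg <- wfConfig(dir)
  runSimulate(cfg)
  runEmbed(cfg)
  expect_true(file.exists(file.path(dir, "embedding_header.json")))
  res <- runTrain(cfg)
  expect_true(file.exists(file.path(dir, "checkpoint.rds")))
  expect_true(file.exists(file.path(dir, "history.tsv")))
  ev1 <- runEvaluate(cfg)
  rep <- read.delim(file.path(dir, "report.tsv"))
  expect_identical(colnames(rep),
                   c("Method", "Genus", "Family", "Order", "Class", "Phylum"))
  md5 <- tools::md5sum(file.path(dir, "report.tsv"))
  ev2 <- runEvaluate(cfg)
  expect_identical(unname(md5),
                   unname(tools::md5sum(file.path(dir, "report.tsv"))))
  expect_identical(rankAccuracies(ev1$report), rankAccuracies(ev2$report))
  expect_true(file.exists(file.path(dir, "rankings.tsv")))
})

test_that("training without a pretrained embedding artifact is a config error", {
  dir <- file.path(tempdir(), "wf-noemb")
  unlink(dir, recursive = TRUE)
  cfg <- wfConfig(dir)
  runSimulate(cfg)
  expect_error(runTrain(cfg), class = "phn_config_error")
})

test_that("ablation flags run through the workflow", {
  dir <- file.path(tempdir(), "wf-abl")
  unlink(dir, recursive = TRUE)
  cfg <- wfConfig(dir, model = list(reduced = TRUE, use_transformer = FALSE))
  runSimulate(cfg)
  runEmbed(cfg)
  res <- runTrain(cfg)
  expect_false(res$model@config$use_transformer)
  cfg2 <- wfConfig(dir, model = list(reduced = TRUE,
                                     use_pretrained_embedding = FALSE))
  res2 <- runTrain(cfg2)
  expect_true("emb.E" %in% names(modelParameters(res2$model)))
})

test_that("checkpoints round-trip with identical predictions", {
  ds <- smallDataset(seed = 17, host_length = 200, phage_length = 200)
  seqs <- as.character(genomeSequences(ds))
  m <- initModel(tinyModelConfig(), seed = 3)
  tab <- randomEmbedding(3, 4, seed = 2)
  ck <- tempfile(fileext = ".rds")
  saveCheckpoint(m, tab, ck)
  back <- loadCheckpoint(ck)
  p1 <- forwardPair(m, seqs[[1]], seqs[[2]], tab)
  p2 <- forwardPair(back$model, seqs[[1]], seqs[[2]], back$table)
  expect_identical(p1, p2)
  expect_error(loadCheckpoint(tempfile()), class = "phn_data_error")
})

test_that("single-pair prediction wraps the forward pass", {
  m <- initModel(tinyModelConfig(), seed = 3)
  tab <- randomEmbedding(3, 4, seed = 2)
  out <- predictInteraction(m, randomDna(80, 1), randomDna(80, 2), tab)
  expect_equal(out$p_match + out$p_non_match, 1, tolerance = 1e-6)
  expect_true(out$label %in% c("match", "non-match"))
})

test_that("YAML configs are read and merged over defaults", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 99", "synthetic:", "  n_phyla: 3"), f)
  cfg <- readWorkflowConfig(f)
  expect_equal(cfg$seed, 99L)
  expect_equal(cfg$synthetic$n_phyla, 3L)
  expect_equal(cfg$split$test_fraction, 1 / 3)  # default retained
  cfg2 <- readWorkflowConfig(f, seed = 7)
  expect_equal(cfg2$seed, 7L)
  expect_error(readWorkflowConfig(tempfile()), class = "phn_config_error")
})
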