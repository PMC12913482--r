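# Workflow entry points: simulate / embed / train / evaluate stages driven
# by one YAML (or list) configuration with a single global seed fanned out
# per stage, plus run manifests recording config, seeds and file digests.
# A thin command-line wrapper lives in inst/scripts/phagehost.R.

.defaultWorkflowConfig <- function() list(
  seed = 1L,
  output_dir = "phagehostnet_run",
  synthetic = list(negatives_per_positive = 1L),
  split = list(test_fraction = 1 / 3),
  embedding = list(window = 5L, negative = 5L, epochs = 3L),
  model = list(reduced = TRUE),
  training = list(epochs = 12L, learning_rate = 1e-3, batch_size = 4L,
                  l2_coefficient = 1e-4, bn_moving_decay = 0.999)
)

#' Read and normalize a workflow configuration
#'
#' @param config path to a YAML file, or a list. Missing fields fall back
#'   to desk-scale defaults.
#' @param seed optional override of the global seed.
#' @return a nested configuration list.
#' @export
readWorkflowConfig <- function(config, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config))
      .phnStop("config", sprintf("no such config file: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) .phnStop("config", "config must be a list or a YAML path")
  cfg <- utils::modifyList(.defaultWorkflowConfig(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

.modelConfigFromWorkflow <- function(cfg) {
  mc <- cfg$model %||% list()
  reduced <- isTRUE(mc$reduced %||% TRUE)
  mc$reduced <- NULL
  if (reduced) do.call(reducedModelConfig, mc) else do.call(modelConfig, mc)
}

.writeManifest <- function(dir, stage, cfg, seeds, files) {
  digests <- as.list(tools::md5sum(file.path(dir, files)))
  names(digests) <- files
  manifest <- list(tool = "PhageHostNet",
                   version = as.character(utils::packageVersion("PhageHostNet")),
                   stage = stage, config = cfg, seeds = seeds,
                   files = digests)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Verify a run directory against its manifest
#'
#' Recomputes the MD5 digest of every file listed in `manifest.json` and
#' fails if any differs or is missing.
#'
#' @param dir a run directory containing `manifest.json`.
#' @return the parsed manifest, invisibly.
#' @export
verifyManifest <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) .phnStop("data", sprintf("no manifest in %s", dir))
  manifest <- jsonlite::read_json(mp, simplifyVector = TRUE)
  for (f in names(manifest$files)) {
    path <- file.path(dir, f)
    if (!file.exists(path))
      .phnStop("data", sprintf("file listed in manifest is missing: %s", f))
    if (!identical(unname(tools::md5sum(path)), unname(unlist(manifest$files[[f]]))))
      .phnStop("data", sprintf("digest mismatch for %s", f))
  }
  invisible(manifest)
}

#' Materialize a synthetic dataset on disk
#'
#' Runs [simulateDataset()] and writes host/phage FASTA files (80-column
#' wrap), the host lineage table, the labeled pair table, and a manifest.
#' Idempotent: rerunning with the same config reproduces byte-identical
#' tables.
#'
#' @param config workflow config (list or YAML path); the `synthetic`
#'   block holds [syntheticConfig()] fields plus `negatives_per_positive`.
#' @param seed optional global-seed override.
#' @return the dataset directory path, invisibly.
#' @export
runSimulate <- function(config, seed = NULL) {
  cfg <- readWorkflowConfig(config, seed)
  sc <- cfg$synthetic
  npp <- sc$negatives_per_positive %||% 1L
  sc$negatives_per_positive <- NULL
  sc$seed <- stageSeed(cfg$seed, "simulate")
  ds <- simulateDataset(do.call(syntheticConfig, sc),
                        negatives_per_positive = npp)
  dir <- file.path(cfg$output_dir, "dataset")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- as.data.frame(genomeMeta(ds))
  seqs <- as.character(genomeSequences(ds))
  writeGenomes(seqs[m$id[m$role == "host"]], file.path(dir, "hosts.fasta"))
  writeGenomes(seqs[m$id[m$role == "phage"]], file.path(dir, "phages.fasta"))
  write.table(hostLineages(ds), file.path(dir, "host_lineages.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(interactionPairs(ds)),
              file.path(dir, "pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  .writeManifest(dir, "simulate", cfg,
                 list(global = cfg$seed, simulate = sc$seed),
                 c("hosts.fasta", "phages.fasta", "host_lineages.tsv",
                   "pairs.tsv"))
  invisible(dir)
}

#' Load a dataset directory written by [runSimulate()]
#'
#' @param dir the dataset directory.
#' @param verify check file digests against the manifest (default TRUE).
#' @return a [PhageHostDataSet-class].
#' @export
loadDatasetDir <- function(dir, verify = TRUE) {
  if (verify) verifyManifest(dir)
  hosts <- readGenomes(file.path(dir, "hosts.fasta"))
  phages <- readGenomes(file.path(dir, "phages.fasta"))
  hl <- read.delim(file.path(dir, "host_lineages.tsv"),
                   stringsAsFactors = FALSE)
  pairs <- read.delim(file.path(dir, "pairs.tsv"), stringsAsFactors = FALSE)
  pos <- pairs[pairs$label == 1, ]
  trueHost <- stats::setNames(pos$host_id, pos$phage_id)
  if (!all(names(phages) %in% names(trueHost)))
    .phnStop("data", "pairs.tsv lacks a positive pair for some phage")
  hmeta <- data.frame(id = hl$host_id, role = "host", hl[RANKS],
                      true_host_id = NA_character_,
                      stringsAsFactors = FALSE)
  pidx <- match(trueHost[names(phages)], hl$host_id)
  pmeta <- data.frame(id = names(phages), role = "phage",
                      hl[pidx, RANKS],
                      true_host_id = unname(trueHost[names(phages)]),
                      stringsAsFactors = FALSE)
  PhageHostDataSet(c(as.character(hosts), as.character(phages)),
                   rbind(hmeta, pmeta), pairs)
}

# Deterministic phage-level train/test split.
.splitPhages <- function(phageIds, test_fraction, seed) {
  phageIds <- sort(phageIds)
  ntest <- max(1L, floor(length(phageIds) * test_fraction))
  test <- .withSeed(stageSeed(seed, "split"),
                    sort(sample(phageIds, ntest)))
  list(train = setdiff(phageIds, test), test = test)
}

#' Pretrain skip-gram embeddings for a run
#'
#' Builds the skip-gram corpus from the training-split phage genomes plus
#' all host genomes and writes the embedding artifact next to the dataset.
#'
#' @param config workflow config (list or YAML path).
#' @param seed optional global-seed override.
#' @return the embedding path prefix, invisibly.
#' @export
runEmbed <- function(config, seed = NULL) {
  cfg <- readWorkflowConfig(config, seed)
  ds <- loadDatasetDir(file.path(cfg$output_dir, "dataset"))
  m <- as.data.frame(genomeMeta(ds))
  split <- .splitPhages(m$id[m$role == "phage"],
                        cfg$split$test_fraction, cfg$seed)
  mcfg <- .modelConfigFromWorkflow(cfg)
  seqs <- as.character(genomeSequences(ds))
  corpusIds <- c(m$id[m$role == "host"], split$train)
  ec <- cfg$embedding
  table <- trainSkipgram(seqs[corpusIds], k = mcfg$k,
                         dim = ec$dim %||% mcfg$d_embed,
                         window = ec$window %||% 5L,
                         negative = ec$negative %||% 5L,
                         epochs = ec$epochs %||% 3L,
                         seed = stageSeed(cfg$seed, "embed"),
                         segment_length = mcfg$segment_length)
  prefix <- file.path(cfg$output_dir, "embedding")
  writeEmbedding(table, prefix)
  invisible(prefix)
}

#' Save / load a model checkpoint
#'
#' The checkpoint archives the model configuration, all weights, batch-norm
#' state, the embedding table and seed provenance under a versioned header.
#'
#' @param model a [SiameseHostModel-class].
#' @param table the [KmerEmbedding-class] used (or NULL).
#' @param path checkpoint path (RDS).
#' @return `path`, invisibly.
#' @export
saveCheckpoint <- function(model, table, path) {
  saveRDS(list(format = "PhageHostNet-checkpoint-1",
               version = as.character(utils::packageVersion("PhageHostNet")),
               config = model@config, params = model@params,
               state = model@state, embedding = table), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @return for `loadCheckpoint`: list with `model` and `table`.
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) .phnStop("data", sprintf("no checkpoint at %s", path))
  ck <- readRDS(path)
  if (!identical(ck$format, "PhageHostNet-checkpoint-1"))
    .phnStop("format", "unrecognized checkpoint format")
  cfg <- ck$config
  class(cfg) <- c("ModelConfig", "list")
  list(model = new("SiameseHostModel", config = unclass(cfg),
                   params = ck$params, state = ck$state),
       table = ck$embedding)
}

#' Train a model for a run
#'
#' Trains on the training-split pairs per the config's `training` block
#' and writes `checkpoint.rds`, `history.tsv` and a manifest.
#'
#' @param config workflow config (list or YAML path).
#' @param seed optional global-seed override.
#' @return list with `model`, `table`, `history` and the split, invisibly.
#' @export
runTrain <- function(config, seed = NULL) {
  cfg <- readWorkflowConfig(config, seed)
  ds <- loadDatasetDir(file.path(cfg$output_dir, "dataset"))
  m <- as.data.frame(genomeMeta(ds))
  split <- .splitPhages(m$id[m$role == "phage"],
                        cfg$split$test_fraction, cfg$seed)
  mcfg <- .modelConfigFromWorkflow(cfg)
  table <- NULL
  if (mcfg$use_pretrained_embedding) {
    prefix <- file.path(cfg$output_dir, "embedding")
    if (!file.exists(paste0(prefix, "_header.json")))
      .phnStop("config", paste("no pretrained embedding found; run runEmbed()",
                               "first or set model$use_pretrained_embedding = FALSE"))
    table <- readEmbedding(prefix)
    if (table@dim != mcfg$d_embed || table@k != mcfg$k)
      .phnStop("config", sprintf(
        "embedding artifact (k = %d, d = %d) does not match the model config (k = %d, d = %d)",
        table@k, table@dim, mcfg$k, mcfg$d_embed))
  }
  pairs <- as.data.frame(interactionPairs(ds))
  trainPairs <- pairs[pairs$phage_id %in% split$train, ]
  tc <- do.call(trainConfig, utils::modifyList(
    cfg$training %||% list(), list(seed = stageSeed(cfg$seed, "train"))))
  model <- initModel(mcfg, seed = stageSeed(cfg$seed, "init"),
                     bn_moving_decay = tc$bn_moving_decay)
  fit <- trainModel(model, trainPairs,
                    as.character(genomeSequences(ds)), table, tc)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  saveCheckpoint(fit$model, table, file.path(cfg$output_dir, "checkpoint.rds"))
  write.table(fit$history, file.path(cfg$output_dir, "history.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  .writeManifest(cfg$output_dir, "train", cfg,
                 list(global = cfg$seed, init = stageSeed(cfg$seed, "init"),
                      train = tc$seed),
                 c("history.tsv"))
  invisible(list(model = fit$model, table = table, history = fit$history,
                 split = split))
}

#' Evaluate a trained run on its held-out phages
#'
#' Ranks all hosts for every test-split phage, writes the five-rank
#' accuracy report (`report.tsv`, Table layout: Method, Genus..Phylum) and
#' the per-phage rankings, and also reports binary accuracy on the
#' held-out labeled pairs.
#'
#' @param config workflow config (list or YAML path).
#' @param seed optional global-seed override.
#' @return list with `report` ([RankAccuracyReport-class]), `binary`
#'   (held-out pair accuracy) and `rankings`, invisibly.
#' @export
runEvaluate <- function(config, seed = NULL) {
  cfg <- readWorkflowConfig(config, seed)
  ds <- loadDatasetDir(file.path(cfg$output_dir, "dataset"))
  ck <- loadCheckpoint(file.path(cfg$output_dir, "checkpoint.rds"))
  m <- as.data.frame(genomeMeta(ds))
  split <- .splitPhages(m$id[m$role == "phage"],
                        cfg$split$test_fraction, cfg$seed)
  seqs <- as.character(genomeSequences(ds))
  hosts <- seqs[m$id[m$role == "host"]]
  ev <- evaluateTestSet(ck$model, seqs[split$test], hosts,
                        phageTruth(ds), hostLineages(ds), ck$table,
                        train_phage_ids = split$train)
  pairs <- as.data.frame(interactionPairs(ds))
  testPairs <- pairs[pairs$phage_id %in% split$test, ]
  bin <- binaryPairAccuracy(ck$model, testPairs, seqs, ck$table)
  acc <- rankAccuracies(ev$report)
  rep <- data.frame(Method = "PhageHostNet",
                    Genus = acc[["genus"]], Family = acc[["family"]],
                    Order = acc[["order"]], Class = acc[["class"]],
                    Phylum = acc[["phylum"]])
  write.table(rep, file.path(cfg$output_dir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ev$rankings, file.path(cfg$output_dir, "rankings.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(report = ev$report, binary = bin, rankings = ev$rankings,
                 predictions = ev$predictions))
}

#' Predict a single phage-host interaction
#'
#' @param model a trained [SiameseHostModel-class].
#' @param phage,host genome sequences.
#' @param table a [KmerEmbedding-class].
#' @return list: `p_match`, `p_non_match`, `label` ("match"/"non-match").
#' @export
predictInteraction <- function(model, phage, host, table = NULL) {
  p <- forwardPair(model, phage, host, table, mode = "eval")
  list(p_match = unname(p[["p_match"]]),
       p_non_match = unname(p[["p_non_match"]]),
       label = if (p[["p_match"]] >= p[["p_non_match"]]) "match" else "non-match")
}
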