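# The package's reference desk-scale experiment: one seeded end-to-end run
# of the whole pipeline (simulate -> skip-gram -> train -> evaluate) at a
# size that completes on a single CPU in minutes. Used by the examples,
# the test suite and scripts/acceptance.R.

#' Run the desk-scale reference experiment
#'
#' Simulates a four-phylum dataset (two hosts per genus, four phages per
#' host, 20 kb genomes, mimicry 0.9), splits the phages 20 train / 10 test
#' (each phage contributes one positive and one phylum-exclusion negative
#' pair, so 40 training and 20 held-out pairs), pretrains skip-gram
#' embeddings on the training genomes, trains the reduced dual-tower model,
#' and evaluates both held-out binary accuracy and five-rank ranking
#' accuracy over all hosts. Deterministic given `seed`.
#'
#' @param seed global seed; fanned out per stage via [stageSeed()].
#' @param variant `"full"` (default), `"no_transformer"` (segment-mean
#'   aggregation instead of the Transformer encoder) or `"no_skipgram"`
#'   (randomly initialized embedding trained jointly with the classifier).
#' @param epochs training epochs (default 20).
#' @param learning_rate,batch_size,l2_coefficient training protocol for
#'   this scale.
#' @param synthetic optional overrides for [syntheticConfig()] fields.
#' @param verbose print training progress.
#' @return list with `binary` (held-out pair accuracy, n, p_match),
#'   `report` (a [RankAccuracyReport-class] from host ranking),
#'   `history` (training log), `baseline_phylum` (accuracy of the
#'   nearest-composition baseline on the test phages), `train_accuracy`
#'   (final epoch), and the objects (`model`, `table`, `dataset`, `split`).
#' @export
deskScaleExperiment <- function(seed = 1L,
                                variant = c("full", "no_transformer",
                                            "no_skipgram"),
                                epochs = 20L, learning_rate = 1e-3,
                                batch_size = 8L, l2_coefficient = 1e-4,
                                synthetic = list(), verbose = FALSE) {
  variant <- match.arg(variant)
  scfg <- do.call(syntheticConfig,
                  utils::modifyList(list(seed = stageSeed(seed, "simulate")),
                                    synthetic))
  ds <- simulateDataset(scfg)
  m <- as.data.frame(genomeMeta(ds))
  seqs <- as.character(genomeSequences(ds))
  hostIds <- m$id[m$role == "host"]
  phageIds <- sort(m$id[m$role == "phage"])
  split <- .withSeed(stageSeed(seed, "split"), {
    test <- sort(sample(phageIds, 10))
    train <- sort(sample(setdiff(phageIds, test), 20))
    list(train = train, test = test)
  })
  pairs <- as.data.frame(interactionPairs(ds))
  trainPairs <- pairs[pairs$phage_id %in% split$train, ]
  testPairs <- pairs[pairs$phage_id %in% split$test, ]
  mcfg <- switch(variant,
    full = reducedModelConfig(),
    no_transformer = reducedModelConfig(use_transformer = FALSE),
    no_skipgram = reducedModelConfig(use_pretrained_embedding = FALSE))
  table <- NULL
  if (mcfg$use_pretrained_embedding)
    table <- trainSkipgram(seqs[c(hostIds, split$train)], k = mcfg$k,
                           dim = mcfg$d_embed, epochs = 3L,
                           seed = stageSeed(seed, "embed"))
  model <- initModel(mcfg, seed = stageSeed(seed, "init"))
  tc <- trainConfig(epochs = epochs, learning_rate = learning_rate,
                    batch_size = batch_size,
                    l2_coefficient = l2_coefficient,
                    seed = stageSeed(seed, "train"))
  fit <- trainModel(model, trainPairs, seqs, table, tc, verbose = verbose)
  binary <- binaryPairAccuracy(fit$model, testPairs, seqs, table)
  ev <- evaluateTestSet(fit$model, seqs[split$test], seqs[hostIds],
                        phageTruth(ds), hostLineages(ds), table,
                        train_phage_ids = split$train)
  base <- nearestCompositionHost(seqs[split$test], seqs[hostIds])
  hl <- hostLineages(ds)
  tr <- phageTruth(ds)
  baselinePhylum <- mean(hl$phylum[match(base, hl$host_id)] ==
                         tr$phylum[match(names(base), tr$phage_id)])
  list(binary = binary, report = ev$report, history = fit$history,
       baseline_phylum = baselinePhylum,
       train_accuracy = fit$history$accuracy[nrow(fit$history)],
       variant = variant, model = fit$model, table = table, dataset = ds,
       split = split, rankings = ev$rankings)
}
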