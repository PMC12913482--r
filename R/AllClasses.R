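# S4 classes for the central data objects.

RANKS <- c("genus", "family", "order", "class", "phylum")

#' PhageHostDataSet: genomes, lineages and labeled pairs
#'
#' Container tying together phage and host genome sequences
#' (a [Biostrings::DNAStringSet] named by genome id), per-genome metadata
#' (role, five-rank taxonomic lineage, and for phages the identity of the
#' true host), and the labeled (phage, host) interaction pairs used for
#' training and testing. For phages the stored lineage is the lineage of the
#' true host (ground truth); hosts carry their own lineage.
#'
#' @slot genomes `DNAStringSet`, named by genome id.
#' @slot meta `DataFrame` with columns `id`, `role` ("phage"/"host"),
#'   `genus`, `family`, `order`, `class`, `phylum`, `true_host_id`.
#' @slot pairs `DataFrame` with columns `phage_id`, `host_id`,
#'   `label` (1 = match, 0 = non-match).
#' @slot profiles list of 64-long 3-mer probability vectors per genus clade
#'   (present for simulated data, may be empty).
#' @slot config list; the generating configuration (may be empty).
#' @export
setClass("PhageHostDataSet",
  representation(genomes = "DNAStringSet", meta = "DataFrame",
                 pairs = "DataFrame", profiles = "list", config = "list"))

.validPhageHostDataSet <- function(object) {
  msg <- character()
  m <- object@meta
  need <- c("id", "role", RANKS, "true_host_id")
  if (!all(need %in% colnames(m)))
    return(paste("meta must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(m$id)) msg <- c(msg, "genome ids must be unique")
  if (!setequal(names(object@genomes), m$id) ||
      length(object@genomes) != nrow(m))
    msg <- c(msg, "genome names must match meta$id")
  if (!all(m$role %in% c("phage", "host")))
    msg <- c(msg, "role must be 'phage' or 'host'")
  hosts <- m[m$role == "host", , drop = FALSE]
  phages <- m[m$role == "phage", , drop = FALSE]
  for (r in RANKS)
    if (any(is.na(hosts[[r]]) | !nzchar(hosts[[r]])))
      msg <- c(msg, sprintf("all hosts need a non-empty '%s'", r))
  if (nrow(phages) && !all(phages$true_host_id %in% hosts$id))
    msg <- c(msg, "every phage's true_host_id must name a host")
  # tree consistency: a genus name determines every coarser rank
  if (nrow(hosts) > 1) {
    key <- do.call(paste, c(as.list(as.data.frame(hosts)[RANKS]), sep = "\r"))
    if (any(tapply(key, hosts$genus, function(z) length(unique(z))) > 1L))
      msg <- c(msg, "lineages are not tree-consistent (a genus maps to several higher lineages)")
  }
  p <- object@pairs
  if (nrow(p)) {
    if (!all(c("phage_id", "host_id", "label") %in% colnames(p)))
      msg <- c(msg, "pairs must have columns phage_id, host_id, label")
    else {
      if (!all(p$phage_id %in% phages$id)) msg <- c(msg, "unknown phage_id in pairs")
      if (!all(p$host_id %in% hosts$id)) msg <- c(msg, "unknown host_id in pairs")
      if (!all(p$label %in% c(0L, 1L))) msg <- c(msg, "pair labels must be 0/1")
      if (anyDuplicated(paste(p$phage_id, p$host_id)))
        msg <- c(msg, "duplicate (phage, host) pairs")
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("PhageHostDataSet", .validPhageHostDataSet)

#' Construct a PhageHostDataSet
#'
#' @param genomes named character vector or `DNAStringSet` of genome
#'   sequences.
#' @param meta data.frame/DataFrame of genome metadata (see class slots).
#' @param pairs data.frame/DataFrame of labeled pairs (may be empty).
#' @param profiles optional list of clade 3-mer profiles.
#' @param config optional generating configuration.
#' @return a validated [PhageHostDataSet-class] object.
#' @export
PhageHostDataSet <- function(genomes, meta, pairs = NULL,
                             profiles = list(), config = list()) {
  if (is.character(genomes)) genomes <- Biostrings::DNAStringSet(genomes)
  meta <- as(as.data.frame(meta, stringsAsFactors = FALSE), "DataFrame")
  if (is.null(pairs))
    pairs <- DataFrame(phage_id = character(), host_id = character(),
                       label = integer())
  else pairs <- as(as.data.frame(pairs, stringsAsFactors = FALSE), "DataFrame")
  new("PhageHostDataSet", genomes = genomes, meta = meta, pairs = pairs,
      profiles = profiles, config = config)
}

#' KmerEmbedding: skip-gram k-mer vectors
#'
#' Dense d-dimensional vectors for every ACGT k-mer plus the reserved UNK
#' token (last row), whose vector is pinned to zero so that padded or
#' ambiguous windows contribute nothing to segment embeddings.
#'
#' @slot k k-mer length.
#' @slot dim embedding dimension d.
#' @slot vectors (4^k + 1) x d matrix, rownames the vocabulary.
#' @slot params list of training hyperparameters (window, negative, epochs,
#'   seed, ...).
#' @export
setClass("KmerEmbedding",
  representation(k = "integer", dim = "integer", vectors = "matrix",
                 params = "list"))

setValidity("KmerEmbedding", function(object) {
  msg <- character()
  vocab <- buildVocabulary(object@k)
  if (nrow(object@vectors) != length(vocab))
    msg <- c(msg, sprintf("vectors must have %d rows", length(vocab)))
  else if (!identical(rownames(object@vectors), vocab))
    msg <- c(msg, "rownames(vectors) must equal buildVocabulary(k)")
  if (ncol(object@vectors) != object@dim)
    msg <- c(msg, "ncol(vectors) must equal dim")
  unk <- object@vectors[nrow(object@vectors), ]
  if (any(unk != 0)) msg <- c(msg, "UNK vector must be all zeros")
  if (length(msg)) msg else TRUE
})

#' SiameseHostModel: the dual-tower network
#'
#' Holds every learnable parameter of the model (convolutional towers,
#' Transformer encoders with their CLS vectors, fusion MLP) together with
#' its architectural configuration and non-learnable state (batch-norm
#' moving statistics, optimizer state after training).
#'
#' @slot config a `ModelConfig` list from [modelConfig()].
#' @slot params named list of parameter arrays.
#' @slot state named list: batch-norm moving statistics and bookkeeping.
#' @export
setClass("SiameseHostModel",
  representation(config = "list", params = "list", state = "list"))

#' RankAccuracyReport: per-rank hierarchical accuracy
#'
#' Accuracy of host prediction scored at the five taxonomic ranks
#' genus, family, order, class, phylum.
#'
#' @slot nTotal number of scored predictions.
#' @slot accuracy named numeric of length 5 (fractions in [0, 1]).
#' @export
setClass("RankAccuracyReport",
  representation(nTotal = "integer", accuracy = "numeric"))

setValidity("RankAccuracyReport", function(object) {
  msg <- character()
  if (!identical(names(object@accuracy), RANKS))
    msg <- c(msg, "accuracy must be named genus, family, order, class, phylum")
  if (any(object@accuracy < -1e-12 | object@accuracy > 1 + 1e-12))
    msg <- c(msg, "accuracies must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

RankAccuracyReport <- function(nTotal, accuracy) {
  new("RankAccuracyReport", nTotal = as.integer(nTotal),
      accuracy = accuracy[RANKS])
}
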