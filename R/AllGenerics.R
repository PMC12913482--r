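# Generics, accessors and show methods.

#' @describeIn PhageHostDataSet-class genome sequences as a `DNAStringSet`.
#' @param x,object a `PhageHostDataSet`.
#' @export
setGeneric("genomeSequences", function(x) standardGeneric("genomeSequences"))
#' @export
setMethod("genomeSequences", "PhageHostDataSet", function(x) x@genomes)

#' @describeIn PhageHostDataSet-class per-genome metadata `DataFrame`.
#' @export
setGeneric("genomeMeta", function(x) standardGeneric("genomeMeta"))
#' @export
setMethod("genomeMeta", "PhageHostDataSet", function(x) x@meta)

#' @describeIn PhageHostDataSet-class labeled (phage, host) pairs.
#' @export
setGeneric("interactionPairs", function(x) standardGeneric("interactionPairs"))
#' @export
setMethod("interactionPairs", "PhageHostDataSet", function(x) x@pairs)

#' @describeIn PhageHostDataSet-class host lineage table
#'   (`host_id` + the five ranks).
#' @export
setGeneric("hostLineages", function(x) standardGeneric("hostLineages"))
#' @export
setMethod("hostLineages", "PhageHostDataSet", function(x) {
  m <- as.data.frame(x@meta)
  h <- m[m$role == "host", c("id", RANKS)]
  names(h)[1] <- "host_id"
  rownames(h) <- NULL
  h
})

#' @describeIn PhageHostDataSet-class true-host lineage table for phages
#'   (`phage_id`, `true_host_id` + the five ranks of the true host).
#' @export
setGeneric("phageTruth", function(x) standardGeneric("phageTruth"))
#' @export
setMethod("phageTruth", "PhageHostDataSet", function(x) {
  m <- as.data.frame(x@meta)
  p <- m[m$role == "phage", c("id", "true_host_id", RANKS)]
  names(p)[1] <- "phage_id"
  rownames(p) <- NULL
  p
})

#' @describeIn PhageHostDataSet-class clade 3-mer profiles (simulated data).
#' @export
setGeneric("cladeProfiles", function(x) standardGeneric("cladeProfiles"))
#' @export
setMethod("cladeProfiles", "PhageHostDataSet", function(x) x@profiles)

setMethod("show", "PhageHostDataSet", function(object) {
  m <- object@meta
  cat("PhageHostDataSet\n")
  cat(sprintf("  %d genomes (%d phages, %d hosts), %d labeled pairs\n",
              nrow(m), sum(m$role == "phage"), sum(m$role == "host"),
              nrow(object@pairs)))
  ph <- unique(m$phylum[m$role == "host"])
  cat(sprintf("  host phyla: %s\n", paste(ph, collapse = ", ")))
})

#' @describeIn KmerEmbedding-class the k-mer length.
#' @param x,object a `KmerEmbedding`.
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))
#' @export
setMethod("kmerSize", "KmerEmbedding", function(x) x@k)

#' @describeIn KmerEmbedding-class the embedding dimension d.
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))
#' @export
setMethod("embeddingDim", "KmerEmbedding", function(x) x@dim)

#' @describeIn KmerEmbedding-class the (4^k + 1) x d matrix of vectors.
#' @export
setGeneric("embeddingVectors", function(x) standardGeneric("embeddingVectors"))
#' @export
setMethod("embeddingVectors", "KmerEmbedding", function(x) x@vectors)

setMethod("show", "KmerEmbedding", function(object) {
  cat(sprintf("KmerEmbedding: k = %d, d = %d (%d tokens incl. UNK)\n",
              object@k, object@dim, nrow(object@vectors)))
})

#' @describeIn SiameseHostModel-class the model configuration list.
#' @param x,object a `SiameseHostModel`.
#' @export
setGeneric("modelConfiguration", function(x) standardGeneric("modelConfiguration"))
#' @export
setMethod("modelConfiguration", "SiameseHostModel", function(x) x@config)

#' @describeIn SiameseHostModel-class named list of parameter arrays.
#' @export
setGeneric("modelParameters", function(x) standardGeneric("modelParameters"))
#' @export
setMethod("modelParameters", "SiameseHostModel", function(x) x@params)

#' Total number of learnable parameters
#' @param x a `SiameseHostModel`.
#' @return integer count of scalar parameters.
#' @export
setGeneric("parameterCount", function(x) standardGeneric("parameterCount"))
#' @export
setMethod("parameterCount", "SiameseHostModel", function(x)
  sum(vapply(x@params, length, integer(1))))

setMethod("show", "SiameseHostModel", function(object) {
  cfg <- object@config
  cat("SiameseHostModel (dual-tower CNN + Transformer)\n")
  cat(sprintf("  segment %d bp, k = %d, d_embed = %d, tower dim = %d\n",
              cfg$segment_length, cfg$k, cfg$d_embed, cfg$tower_dim))
  cat(sprintf("  %d Transformer layers x %d heads (head dim %d); MLP hidden %d\n",
              cfg$n_transformer_layers, cfg$n_heads, cfg$head_dim,
              cfg$mlp_hidden))
  cat(sprintf("  %s parameters; trained steps: %d\n",
              format(parameterCount(object), big.mark = ","),
              object@state$steps %||% 0L))
})

#' @describeIn RankAccuracyReport-class accuracies as a named numeric vector.
#' @param x,object a `RankAccuracyReport`.
#' @export
setGeneric("rankAccuracies", function(x) standardGeneric("rankAccuracies"))
#' @export
setMethod("rankAccuracies", "RankAccuracyReport", function(x) x@accuracy)

#' @describeIn RankAccuracyReport-class number of scored predictions.
#' @export
setGeneric("nScored", function(x) standardGeneric("nScored"))
#' @export
setMethod("nScored", "RankAccuracyReport", function(x) x@nTotal)

setMethod("show", "RankAccuracyReport", function(object) {
  cat(sprintf("RankAccuracyReport (n = %d)\n", object@nTotal))
  print(round(object@accuracy, 4))
})

#' @export
as.data.frame.RankAccuracyReport <- function(x, ...) {
  data.frame(rank = names(x@accuracy), accuracy = unname(x@accuracy),
             n_total = x@nTotal)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
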