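# Evaluation: host ranking per phage, binary pair accuracy, and per-rank
# hierarchical accuracy (genus, family, order, class, phylum).

# Global host/phage tower vectors, computed once per genome in eval mode.
.globalVectors <- function(model, seqs, tower, table) {
  vapply(as.character(seqs),
         function(s) .towerForward(model, s, tower, table, "eval")$global,
         numeric(model@config$tower_dim))
}

#' Rank candidate hosts for one phage
#'
#' Scores every (phage, candidate) pair with the model's match probability
#' and returns the full ranking, sorted by descending `p_match` with ties
#' broken by lexicographic host id. The top-ranked candidate is the
#' predicted host.
#'
#' @param model a trained [SiameseHostModel-class].
#' @param phage phage genome sequence.
#' @param candidates named character vector (or `DNAStringSet`) of
#'   candidate host genomes.
#' @param table a [KmerEmbedding-class].
#' @return data.frame with columns `host_id`, `p_match` (sorted
#'   non-increasing); attributes `phage_id` (if `phage` is named) and
#'   `predicted_host_id`.
#' @export
rankHosts <- function(model, phage, candidates, table = NULL) {
  if (length(candidates) == 0)
    .phnStop("contract", "candidate list must be non-empty")
  if (is.null(names(candidates)) || any(!nzchar(names(candidates))))
    .phnStop("contract", "candidates must be named by host id")
  Ch <- .globalVectors(model, candidates, "host", table)
  Cp <- .towerForward(model, as.character(phage), "phage", table, "eval")$global
  p <- vapply(seq_len(ncol(Ch)),
              function(j) fuseAndClassify(Cp, Ch[, j], model)[["p_match"]],
              numeric(1))
  ids <- names(candidates)
  ord <- order(-p, ids)
  out <- data.frame(host_id = ids[ord], p_match = p[ord],
                    stringsAsFactors = FALSE)
  attr(out, "predicted_host_id") <- out$host_id[1]
  out
}

#' Hierarchical (five-rank) prediction accuracy
#'
#' For each taxonomic rank L, the fraction of phages whose predicted
#' host's name at L equals the true host's name at L. With tree-consistent
#' lineages the accuracies are monotone non-decreasing from genus to
#' phylum.
#'
#' @param predictions data.frame with `phage_id`, `predicted_host_id`.
#' @param truth data.frame with `phage_id` and the five rank columns of
#'   each phage's true host (see [phageTruth()]).
#' @param host_lineages data.frame with `host_id` and the five rank
#'   columns (see [hostLineages()]).
#' @return a [RankAccuracyReport-class].
#' @export
hierarchicalAccuracy <- function(predictions, truth, host_lineages) {
  predictions <- as.data.frame(predictions)
  truth <- as.data.frame(truth)
  host_lineages <- as.data.frame(host_lineages)
  n <- nrow(predictions)
  if (n == 0) .phnStop("contract", "no predictions to score")
  ti <- match(predictions$phage_id, truth$phage_id)
  if (anyNA(ti))
    .phnStop("data", sprintf("no true-host lineage for phage(s): %s",
      paste(predictions$phage_id[is.na(ti)], collapse = ", ")))
  hi <- match(predictions$predicted_host_id, host_lineages$host_id)
  if (anyNA(hi))
    .phnStop("data", sprintf("no lineage for predicted host(s): %s",
      paste(unique(predictions$predicted_host_id[is.na(hi)]), collapse = ", ")))
  acc <- vapply(RANKS, function(r)
    sum(truth[[r]][ti] == host_lineages[[r]][hi]) / n, numeric(1))
  RankAccuracyReport(n, acc)
}

#' Binary match/non-match accuracy on labeled pairs
#'
#' Scores each labeled pair in eval mode and reports the fraction where
#' the argmax class equals the label.
#'
#' @param model a trained [SiameseHostModel-class].
#' @param pairs data.frame with `phage_id`, `host_id`, `label`.
#' @param genomes named character vector or `DNAStringSet`.
#' @param table a [KmerEmbedding-class].
#' @return list: `accuracy`, `n`, and per-pair `p_match`.
#' @export
binaryPairAccuracy <- function(model, pairs, genomes, table = NULL) {
  pairs <- as.data.frame(pairs)
  genomes <- stats::setNames(as.character(genomes), names(genomes))
  ids <- unique(c(pairs$phage_id, pairs$host_id))
  missing <- setdiff(ids, names(genomes))
  if (length(missing))
    .phnStop("data", sprintf("pair ids without genomes: %s",
                             paste(missing, collapse = ", ")))
  Cp <- .globalVectors(model, genomes[unique(pairs$phage_id)], "phage", table)
  colnames(Cp) <- unique(pairs$phage_id)
  Ch <- .globalVectors(model, genomes[unique(pairs$host_id)], "host", table)
  colnames(Ch) <- unique(pairs$host_id)
  pm <- vapply(seq_len(nrow(pairs)), function(i)
    fuseAndClassify(Cp[, pairs$phage_id[i]], Ch[, pairs$host_id[i]],
                    model)[["p_match"]], numeric(1))
  pred <- as.integer(pm > 0.5)
  list(accuracy = mean(pred == pairs$label), n = nrow(pairs), p_match = pm)
}

#' Evaluate a model on a held-out test set by host ranking
#'
#' For every test phage, ranks all candidate hosts (host tower vectors are
#' computed once and shared across phages), takes the top-1 candidate as
#' the predicted host, and scores hierarchical accuracy at the five ranks.
#'
#' @param model a trained [SiameseHostModel-class].
#' @param phages named character vector (or `DNAStringSet`) of test phage
#'   genomes.
#' @param candidates named character vector (or `DNAStringSet`) of
#'   candidate host genomes.
#' @param truth true-host lineage table (see [hierarchicalAccuracy()]).
#' @param host_lineages candidate lineage table.
#' @param table a [KmerEmbedding-class].
#' @param train_phage_ids optional ids used in training; any overlap with
#'   the test phages is a protocol error.
#' @return list: `report` (a [RankAccuracyReport-class]), `predictions`,
#'   and `rankings` (long data.frame with per-phage candidate scores).
#' @export
evaluateTestSet <- function(model, phages, candidates, truth, host_lineages,
                            table = NULL, train_phage_ids = NULL) {
  if (length(phages) == 0) .phnStop("contract", "no test phages")
  if (length(candidates) == 0) .phnStop("contract", "no candidate hosts")
  overlap <- intersect(names(phages), train_phage_ids)
  if (length(overlap))
    .phnStop("protocol", sprintf(
      "test phages overlap the training set: %s", paste(overlap, collapse = ", ")))
  Ch <- .globalVectors(model, candidates, "host", table)
  colnames(Ch) <- names(candidates)
  rankings <- list()
  predictions <- data.frame(phage_id = character(),
                            predicted_host_id = character())
  for (pid in names(phages)) {
    Cp <- .towerForward(model, as.character(phages[[pid]]), "phage", table,
                        "eval")$global
    p <- vapply(colnames(Ch),
                function(h) fuseAndClassify(Cp, Ch[, h], model)[["p_match"]],
                numeric(1))
    ord <- order(-p, colnames(Ch))
    rankings[[pid]] <- data.frame(phage_id = pid,
                                  host_id = colnames(Ch)[ord],
                                  p_match = unname(p[ord]),
                                  rank = seq_along(p),
                                  stringsAsFactors = FALSE)
    predictions <- rbind(predictions, data.frame(
      phage_id = pid, predicted_host_id = colnames(Ch)[ord][1],
      stringsAsFactors = FALSE))
  }
  list(report = hierarchicalAccuracy(predictions, truth, host_lineages),
       predictions = predictions,
       rankings = do.call(rbind, c(rankings, list(make.row.names = FALSE))))
}
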