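# k-mer vocabulary and skip-gram embeddings.
#
# One shared vocabulary/embedding serves both phage and host genomes. The
# skip-gram model (negative sampling, single worker) is trained on the
# pooled tokenized segments of the training genomes; the UNK token is
# excluded from training and its vector is pinned to zero so that padded
# positions contribute zero rows to segment embeddings.

#' Build the ordered k-mer vocabulary
#'
#' All 4^k ACGT k-mers in lexicographic order (A < C < G < T), followed by
#' the reserved `"UNK"` token.
#'
#' @param k k-mer length, 1..8.
#' @return character vector of 4^k + 1 tokens.
#' @export
#' @examples
#' buildVocabulary(1)
buildVocabulary <- function(k = 3L) {
  if (!.isCount(k) || k > 8) .phnStop("config", "k must be an integer in 1..8")
  b <- c("A", "C", "G", "T")
  v <- b
  if (k > 1) for (i in 2:k) v <- as.vector(t(outer(v, b, paste0)))
  c(v, "UNK")
}

# Tokenize whole genomes into a skip-gram corpus: one integer id vector per
# 2 kb segment, UNK tokens removed.
.buildCorpus <- function(sequences, k = 3L, segment_length = 2000L) {
  unk <- as.integer(4^k + 1)
  out <- list()
  for (s in as.character(sequences)) {
    segs <- segmentGenome(s, segment_length)
    for (seg in segs) {
      ids <- .tokenIds(seg, k)
      ids <- ids[ids != unk]
      if (length(ids) > 1) out[[length(out) + 1L]] <- ids
    }
  }
  out
}

#' Train skip-gram k-mer embeddings
#'
#' Trains a skip-gram model with negative sampling over a tokenized genome
#' corpus, so that k-mers occurring in similar contexts acquire similar
#' vectors. Deterministic given `seed` (single-threaded).
#'
#' @param corpus either a list of token vectors (integer ids or character
#'   k-mers), or a named character vector / `DNAStringSet` of genome
#'   sequences which are segmented and tokenized internally.
#' @param k k-mer length (default 3).
#' @param dim embedding dimension d (default 64).
#' @param window context window half-width (default 5).
#' @param negative negative samples per positive (default 5).
#' @param epochs passes over the corpus (default 5).
#' @param alpha,alpha_min initial and floor learning rate.
#' @param seed RNG seed.
#' @param segment_length used when `corpus` is raw sequences.
#' @return a [KmerEmbedding-class].
#' @export
trainSkipgram <- function(corpus, k = 3L, dim = 64L, window = 5L,
                          negative = 5L, epochs = 5L, alpha = 0.025,
                          alpha_min = 1e-4, seed = 1L,
                          segment_length = 2000L) {
  for (nm in c("dim", "window", "negative", "epochs"))
    .assertCount(get(nm), nm)
  vocab <- buildVocabulary(k)
  nv <- as.integer(4^k)
  unk <- nv + 1L
  if (is.character(corpus) || methods::is(corpus, "XStringSet"))
    corpus <- .buildCorpus(corpus, k = k, segment_length = segment_length)
  if (!is.list(corpus) || length(corpus) == 0)
    .phnStop("data", "empty skip-gram corpus")
  corpus <- lapply(corpus, function(tok) {
    if (is.character(tok)) tok <- match(tok, vocab)
    tok <- as.integer(tok)
    if (anyNA(tok)) .phnStop("data", "corpus contains tokens outside the vocabulary")
    tok[tok != unk]
  })
  corpus <- corpus[vapply(corpus, length, integer(1)) > 1]
  if (length(corpus) == 0) .phnStop("data", "empty skip-gram corpus")
  W <- .withSeed(seed, cpp_sgns_train(corpus, nv, as.integer(dim),
                                      as.integer(window), as.integer(negative),
                                      as.integer(epochs), alpha, alpha_min))
  vectors <- rbind(W, 0)
  rownames(vectors) <- vocab
  new("KmerEmbedding", k = as.integer(k), dim = as.integer(dim),
      vectors = vectors,
      params = list(window = as.integer(window), negative = as.integer(negative),
                    epochs = as.integer(epochs), seed = as.integer(seed),
                    kind = "skipgram"))
}

#' Randomly initialized k-mer embedding
#'
#' The same shape as a trained [trainSkipgram()] table but with seeded
#' N(0, 0.1) vectors; used by the "without skip-gram" ablation, where the
#' table is trained jointly with the classifier instead of being
#' pretrained. UNK stays pinned at zero.
#'
#' @param k k-mer length.
#' @param dim embedding dimension.
#' @param seed RNG seed.
#' @return a [KmerEmbedding-class].
#' @export
randomEmbedding <- function(k = 3L, dim = 64L, seed = 1L) {
  vocab <- buildVocabulary(k)
  nv <- as.integer(4^k)
  W <- .withSeed(seed, matrix(rnorm(nv * dim, sd = 0.1), nv, dim))
  vectors <- rbind(W, 0)
  rownames(vectors) <- vocab
  new("KmerEmbedding", k = as.integer(k), dim = as.integer(dim),
      vectors = vectors, params = list(seed = as.integer(seed), kind = "random"))
}

#' Embed a tokenized segment as a matrix
#'
#' Row i is the embedding vector of token i; UNK rows are all zero.
#'
#' @param tokens character tokens (from [tokenizeKmers()]) or integer ids.
#' @param table a [KmerEmbedding-class].
#' @return a `length(tokens) x d` numeric matrix.
#' @export
embedSegment <- function(tokens, table) {
  stopifnot(methods::is(table, "KmerEmbedding"))
  if (is.character(tokens)) {
    ids <- match(tokens, rownames(table@vectors))
    if (anyNA(ids))
      .phnStop("data", sprintf("unknown token(s): %s",
        paste(unique(tokens[is.na(ids)]), collapse = ", ")))
  } else {
    ids <- as.integer(tokens)
    if (anyNA(ids) || any(ids < 1 | ids > nrow(table@vectors)))
      .phnStop("data", "token id out of vocabulary range")
  }
  table@vectors[ids, , drop = FALSE]
}

#' Persist an embedding table as plain text
#'
#' Writes three files under `prefix`: `<prefix>_tokens.txt` (ordered token
#' list), `<prefix>_vectors.txt` (whitespace-delimited matrix) and
#' `<prefix>_header.json` (k, d and training hyperparameters).
#'
#' @param table a [KmerEmbedding-class].
#' @param prefix output path prefix.
#' @return the three paths, invisibly.
#' @export
writeEmbedding <- function(table, prefix) {
  stopifnot(methods::is(table, "KmerEmbedding"))
  paths <- paste0(prefix, c("_tokens.txt", "_vectors.txt", "_header.json"))
  writeLines(rownames(table@vectors), paths[1])
  write.table(format(table@vectors, digits = 17, scientific = TRUE,
                     trim = TRUE),
              paths[2], quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(c(list(k = table@k, dim = table@dim), table@params),
                       paths[3], auto_unbox = TRUE)
  invisible(paths)
}

#' Read an embedding table written by [writeEmbedding()]
#'
#' @param prefix the path prefix used when writing.
#' @return a [KmerEmbedding-class].
#' @export
readEmbedding <- function(prefix) {
  paths <- paste0(prefix, c("_tokens.txt", "_vectors.txt", "_header.json"))
  if (!all(file.exists(paths)))
    .phnStop("format", sprintf("missing embedding artifact files at prefix %s", prefix))
  hdr <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  toks <- readLines(paths[1])
  vecs <- as.matrix(read.table(paths[2]))
  dimnames(vecs) <- list(toks, NULL)
  new("KmerEmbedding", k = as.integer(hdr$k), dim = as.integer(hdr$dim),
      vectors = vecs,
      params = hdr[setdiff(names(hdr), c("k", "dim"))])
}
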