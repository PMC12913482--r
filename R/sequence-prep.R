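# Sequence preparation: FASTA I/O, fixed-width segmentation with terminal
# padding, and overlapping k-mer tokenization.
#
# A genome of length N is cut into c = ceiling(N / segment_length) windows;
# only the last window may be padded (with the PAD base 'N'), so that the
# unpadded prefixes concatenate back to the input. Every window is then
# tokenized into (segment_length - k + 1) overlapping k-mers; any window
# touching a non-ACGT symbol (IUPAC ambiguity codes or PAD) becomes the
# reserved UNK token, keeping the row count of the downstream embedding
# matrix fixed.

PAD_BASE <- "N"

#' Read genome sequences from a FASTA file
#'
#' Sequences are uppercased; the header token before the first whitespace
#' becomes the genome id. Zero-length entries and duplicated ids are
#' rejected.
#'
#' @param path path to a FASTA file.
#' @return a named `DNAStringSet`.
#' @export
readGenomes <- function(path) {
  if (!file.exists(path)) .phnStop("format", sprintf("no such file: %s", path))
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) .phnStop("format",
                   sprintf("malformed FASTA '%s': %s", path, conditionMessage(e))))
  if (length(ss) == 0) .phnStop("format", sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(ss))
  if (any(!nzchar(ids))) .phnStop("format", "FASTA entry with empty header id")
  if (anyDuplicated(ids))
    .phnStop("format", sprintf("duplicated FASTA ids: %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  w <- Biostrings::width(ss)
  if (any(w == 0))
    .phnStop("format", sprintf("zero-length sequence for entry '%s'",
                               ids[which(w == 0)[1]]))
  out <- Biostrings::DNAStringSet(toupper(as.character(ss)))
  names(out) <- ids
  out
}

#' Write genome sequences to FASTA (80-column wrap)
#'
#' @param genomes named character vector or `DNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenomes <- function(genomes, path) {
  if (is.character(genomes)) genomes <- Biostrings::DNAStringSet(genomes)
  Biostrings::writeXStringSet(genomes, filepath = path, width = 80L)
  invisible(path)
}

#' Segment a genome into fixed-length windows with terminal padding
#'
#' @param sequence a character scalar (or anything coercible via
#'   `as.character`, e.g. a `DNAString`).
#' @param segment_length window width in bp (default 2000).
#' @return a character vector of `ceiling(N / segment_length)` strings, each
#'   exactly `segment_length` characters; attribute `pad_lengths` gives the
#'   per-segment count of padded positions (non-zero only for the last).
#' @export
#' @examples
#' s <- segmentGenome(strrep("ACGT", 1100))  # 4400 bp -> 3 segments
#' attr(s, "pad_lengths")
segmentGenome <- function(sequence, segment_length = 2000L) {
  sequence <- as.character(sequence)
  if (length(sequence) != 1 || is.na(sequence) || !nzchar(sequence))
    .phnStop("contract", "sequence must be a single non-empty string")
  .assertCount(segment_length, "segment_length")
  n <- nchar(sequence)
  cseg <- ceiling(n / segment_length)
  starts <- (seq_len(cseg) - 1L) * segment_length + 1L
  segs <- substring(sequence, starts, pmin(starts + segment_length - 1L, n))
  pads <- segment_length - nchar(segs)
  if (pads[cseg] > 0)
    segs[cseg] <- paste0(segs[cseg], strrep(PAD_BASE, pads[cseg]))
  attr(segs, "pad_lengths") <- as.integer(pads)
  segs
}

# Fast path: integer token ids (1..4^k for ACGT k-mers in lexicographic
# order, 4^k + 1 for UNK) for all overlapping windows of a segment.
.tokenIds <- function(segment, k = 3L) {
  x <- utf8ToInt(segment)
  codes <- rep(NA_integer_, 128L)
  codes[utf8ToInt("A")] <- 0L; codes[utf8ToInt("C")] <- 1L
  codes[utf8ToInt("G")] <- 2L; codes[utf8ToInt("T")] <- 3L
  v <- codes[x]
  n <- length(v) - k + 1L
  if (n < 1L) .phnStop("contract", "segment shorter than k")
  id <- integer(n)
  for (i in seq_len(k)) id <- id * 4L + v[i:(i + n - 1L)]
  unk <- as.integer(4^k + 1)
  id <- id + 1L
  id[is.na(id)] <- unk
  id
}

#' Tokenize a fixed-length segment into overlapping k-mers
#'
#' The i-th token is the substring `[i, i + k)`. Windows containing any
#' non-ACGT symbol (ambiguity codes, PAD) map to the reserved `"UNK"` token.
#'
#' @param segment a string of exactly `expected_length` characters.
#' @param k k-mer length (default 3).
#' @param expected_length required segment length (default 2000); a
#'   mismatch is a contract error.
#' @return character vector of `expected_length - k + 1` tokens.
#' @export
#' @examples
#' head(tokenizeKmers(strrep("ACGT", 500)))
tokenizeKmers <- function(segment, k = 3L, expected_length = 2000L) {
  if (length(segment) != 1 || !is.character(segment))
    .phnStop("contract", "segment must be a single string")
  if (nchar(segment) != expected_length)
    .phnStop("contract", sprintf(
      "segment length %d != expected %d", nchar(segment), expected_length))
  if (!.isCount(k) || k > nchar(segment))
    .phnStop("config", "k must be a positive integer <= segment length")
  buildVocabulary(k)[.tokenIds(segment, as.integer(k))]
}
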