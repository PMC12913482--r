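test_that("segmentation produces ceiling(N/2000) windows with terminal padding only", {
  cases <- data.frame(n = c(1L, 1999L, 2000L, 2001L, 4001L),
                      segs = c(1L, 1L, 1L, 2L, 3L),
                      lastPad = c(1999L, 1L, 0L, 1999L, 1999L))
  for (i in seq_len(nrow(cases))) {
    s <- randomDna(cases$n[i], seed = i)
    segs <- segmentGenome(s)
    pads <- attr(segs, "pad_lengths")
    expect_length(segs, cases$segs[i])
    expect_true(all(nchar(segs) == 2000L))
    expect_equal(pads[length(pads)], cases$lastPad[i])
    expect_true(all(pads[-length(pads)] == 0L))
    # concatenating the unpadded prefixes reconstructs the input
    prefixes <- substr(segs, 1L, 2000L - pads)
    expect_identical(paste(prefixes, collapse = ""), s)
  }
})

test_that("segmentation respects non-default window widths", {
  s <- randomDna(2500, seed = 5)
  segs <- segmentGenome(s, segment_length = 1000L)
  expect_length(segs, 3L)
  expect_true(all(nchar(segs) == 1000L))
  expect_error(segmentGenome(""), class = "phn_contract_error")
})

test_that("tokenization slides a k-window and maps padded/ambiguous windows to UNK", {
  s <- randomDna(2000, seed = 9)
  tok <- tokenizeKmers(s)
  expect_length(tok, 1998L)
  expect_identical(tok[1:3], c(substr(s, 1, 3), substr(s, 2, 4), substr(s, 3, 5)))
  # a segment ending in two PAD symbols: the last two windows become UNK
  padded <- paste0(substr(s, 1, 1998), "NN")
  tokp <- tokenizeKmers(padded)
  expect_identical(tokp[1997:1998], c("UNK", "UNK"))
  expect_false("UNK" %in% tokp[1:1996])
  # IUPAC ambiguity letters inside the sequence also become UNK windows
  amb <- paste0("ACGR", substr(s, 5, 2000))
  toka <- tokenizeKmers(amb)
  expect_identical(toka[2:4], c("UNK", "UNK", "UNK"))
  expect_identical(toka[1], "ACG")
  expect_error(tokenizeKmers(substr(s, 1, 100)), class = "phn_contract_error")
})

test_that("tokenization is position-faithful on random segments", {
  for (seed in 1:3) {
    s <- randomDna(2000, seed = 100 + seed)
    tok <- tokenizeKmers(s)
    idx <- sample(1998, 50)
    expect_identical(tok[idx],
                     vapply(idx, function(i) substr(s, i, i + 2), ""))
    # base i is recoverable from the first character of token i
    i <- sample(1998, 20)
    expect_identical(substr(tok[i], 1, 1), vapply(i, function(j) substr(s, j, j), ""))
  }
})

test_that("segment+tokenize composition preserves the brute-force window count", {
  for (n in c(2000L, 4001L, 5000L, 7321L)) {
    s <- randomDna(n, seed = n)
    segs <- segmentGenome(s)
    toks <- unlist(lapply(segs, tokenizeKmers))
    cseg <- length(segs)
    # exact per-segment window count: max(len - k + 1, 0) real windows
    lens <- 2000L - attr(segs, "pad_lengths")
    expect_equal(sum(toks != "UNK"), sum(pmax(lens - 2L, 0L)))
    # when the last segment is at least k long this equals N - (k-1)c
    if (lens[cseg] >= 3L) expect_equal(sum(toks != "UNK"), n - 2L * cseg)
    expect_length(toks, cseg * 1998L)
  }
})

test_that("FASTA round trip preserves ids and sequences, uppercasing input", {
  f <- tempfile(fileext = ".fasta")
  seqs <- c(g1 = randomDna(180, seed = 1), g2 = randomDna(95, seed = 2))
  writeGenomes(seqs, f)
  expect_true(any(nchar(readLines(f)) <= 80))
  back <- readGenomes(f)
  expect_identical(names(back), c("g1", "g2"))
  expect_identical(unname(as.character(back)), unname(seqs))
  # lowercase input is normalized; header is cut at first whitespace
  writeLines(c(">low extra description", "acgtacgt"), f)
  low <- readGenomes(f)
  expect_identical(names(low), "low")
  expect_identical(unname(as.character(low)), "ACGTACGT")
})

test_that("malformed FASTA inputs raise format errors", {
  f <- tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_error(readGenomes(f), class = "phn_format_error")
  writeLines(c(">a", "ACGT", ">empty", ">b", "ACGT"), f)
  expect_error(readGenomes(f), class = "phn_format_error")
  expect_error(readGenomes(tempfile()), class = "phn_format_error")
})
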