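test_that("basic index records every fully indexable window once", {
  b <- make_block(c(s1 = "ARN"))
  idx <- build_basic_index(b)
  expect_equal(sum(diff(idx$word_start)), 1L)
  expect_equal(plain(word_positions(idx, "ARN")),
               plain(tibble::tibble(seq_id = 0L, subject_offset = 0L)))

  # overlapping words
  b2 <- make_block(c(s1 = "ARAR"))
  idx2 <- build_basic_index(b2)
  expect_equal(plain(word_positions(idx2, "ARA")),
               plain(tibble::tibble(seq_id = 0L, subject_offset = 0L)))
  expect_equal(plain(word_positions(idx2, "RAR")),
               plain(tibble::tibble(seq_id = 0L, subject_offset = 1L)))

  # counting oracle over a random block with masked residues
  set.seed(41)
  strs <- random_db_strings(25, 3, 50)
  strs[3] <- paste0(substr(strs[3], 1, 10), "XX", substr(strs[3], 13, 50))
  b3 <- make_block(strs)
  idx3 <- build_basic_index(b3)
  expected <- sum(vapply(b3$seqs, function(s) {
    if (length(s) < 3L) return(0L)
    sum(vapply(0:(length(s) - 3L), function(p)
      all(s[(p + 1):(p + 3)] < 20L), NA))
  }, 0L))
  expect_equal(length(idx3$offset), expected)
})

test_that("sort_positions orders per word by (offset, seq_id), stably", {
  # hand case via a block engineered to interleave sequences
  b <- make_block(c(a = "ARNARN", bb = "GGARNG"))
  idx <- sort_positions(build_basic_index(b))
  p <- word_positions(idx, "ARN")
  expect_true(!is.unsorted(p$subject_offset))
  ord <- order(p$subject_offset, p$seq_id)
  expect_identical(ord, seq_along(ord))

  # idempotence
  idx2 <- sort_positions(idx)
  expect_identical(idx2$offset, idx$offset)
  expect_identical(idx2$seq_id, idx$seq_id)

  # permutation + order property on a random block
  set.seed(43)
  b3 <- make_block(random_db_strings(30, 10, 60))
  raw <- build_basic_index(b3)
  srt <- sort_positions(raw)
  for (w in sample(which(diff(raw$word_start) > 1L), 10) - 1L) {
    pr <- word_positions(raw, w)
    ps <- word_positions(srt, w)
    expect_same_rows(pr, ps)
    expect_true(!is.unsorted(ps$subject_offset))
  }
})

test_that("compression merges repeated offsets and delta-encodes", {
  # a word at offset 0 of two sequences collapses to one entry
  ent <- compress_positions(
    tibble::tibble(seq_id = c(1L, 3L), subject_offset = c(0L, 0L)))
  expect_equal(ent$delta, 0L)
  expect_equal(ent$count, 2L)
  expect_equal(ent$seq_ids[[1]], c(1L, 3L))

  # delta arithmetic
  ent2 <- compress_positions(
    tibble::tibble(seq_id = c(0L, 1L, 2L), subject_offset = c(2L, 5L, 5L)))
  expect_equal(ent2$delta, c(2L, 3L))
  expect_equal(ent2$count, c(1L, 2L))
  expect_equal(ent2$seq_ids, list(0L, c(1L, 2L)))

  expect_error(compress_positions(
    tibble::tibble(seq_id = c(0L, 0L), subject_offset = c(5L, 2L))),
    "sorted")

  # round trip on fuzzed sorted positions
  set.seed(47)
  for (i in 1:25) {
    n <- sample(1:200, 1)
    pos <- tibble::tibble(
      seq_id = sample(0:20, n, TRUE),
      subject_offset = sort(sample(0:600, n, TRUE)))
    pos <- pos[order(pos$subject_offset, pos$seq_id), ]
    dec <- decode_positions(compress_positions(pos))
    expect_equal(plain(dec), plain(pos))
  }
})

test_that("overflow splitting respects the 8-bit fields and is lossless", {
  sp <- split_overflow(300L, 25L, 1:25)
  expect_equal(sp$delta, c(255L, 45L))
  expect_equal(sp$count, c(0L, 25L))

  sp2 <- split_overflow(2L, 300L, 1:300)
  expect_equal(sp2$delta, c(2L, 0L))
  expect_equal(sp2$count, c(255L, 45L))
  expect_equal(sp2$seq_ids[[1]], 1:255)
  expect_equal(sp2$seq_ids[[2]], 256:300)

  sp3 <- split_overflow(600L, 1L, 7L)
  expect_equal(sp3$delta, c(255L, 255L, 90L))
  dec <- decode_positions(sp3)
  expect_equal(dec$subject_offset, 600L)
  expect_equal(dec$seq_id, 7L)

  # all fields bounded after splitting, for arbitrary inputs
  set.seed(53)
  for (i in 1:20) {
    d <- sample(0:2000, 1); k <- sample(1:700, 1)
    sp <- split_overflow(d, k, seq_len(k))
    expect_true(all(sp$delta <= 255L & sp$count <= 255L))
    dec <- decode_positions(sp)
    expect_equal(unique(dec$subject_offset), d)
    expect_equal(dec$seq_id, seq_len(k))
  }
})

test_that("decode_positions validates entries", {
  expect_equal(nrow(decode_positions(tibble::tibble(
    delta = integer(), count = integer(), seq_ids = list()))), 0L)
  expect_error(decode_positions(tibble::tibble(
    delta = 1L, count = 2L, seq_ids = list(5L))), "count")
  expect_error(decode_positions(tibble::tibble(
    delta = 300L, count = 1L, seq_ids = list(5L))), "255")
})

test_that("block compression agrees with the per-word reference", {
  set.seed(59)
  for (i in 1:5) {
    b <- make_block(random_db_strings(20, 10, 70))
    idx <- build_block_index(b)
    widx <- sort_positions(build_basic_index(b))
    for (w in sample(which(diff(widx$word_start) > 0L), 20) - 1L) {
      ref <- compress_positions(word_positions(widx, w))
      a <- idx$entry_start[w + 1L] + 1L
      bnd <- idx$entry_start[w + 2L]
      expect_equal(idx$delta[a:bnd], ref$delta)
      expect_equal(idx$count[a:bnd], ref$count)
    }
  }
})

test_that("neighbor words match exhaustive scoring", {
  expect_length(compute_neighbor_words("PQG", "BLOSUM62", Inf), 0L)
  expect_length(compute_neighbor_words("PQG", "BLOSUM62", -Inf), 7999L)

  m <- substitution_matrix("BLOSUM62")
  w <- as.integer(encode_residues("PQG"))
  brute <- integer()
  for (id in 0:7999) {
    cs <- integer(3); x <- id
    for (k in 3:1) { cs[k] <- x %% 20L; x <- x %/% 20L }
    sc <- m[w[1] + 1, cs[1] + 1] + m[w[2] + 1, cs[2] + 1] +
      m[w[3] + 1, cs[3] + 1]
    if (sc >= 13 && id != word_id("PQG")) brute <- c(brute, id)
  }
  nb <- compute_neighbor_words("PQG", "BLOSUM62", 13)
  expect_identical(nb, brute)  # ascending, no self
  expect_false(word_id("PQG") %in% compute_neighbor_words("PQG"))
})

test_that("block index decodes to exactly the sorted basic positions", {
  # all sequences shorter than W give an all-empty index
  b0 <- make_block(c(a = "AR", bb = "GG"))
  idx0 <- build_block_index(b0)
  expect_equal(length(idx0$delta), 0L)
  expect_true(all(diff(idx0$entry_start) == 0L))

  # the compressed stream reproduces the offset-merge pattern:
  # a word shared at one offset by two sequences stores the offset once
  b1 <- make_block(c(s0 = "GGGG", s1 = "ACDE", s2 = "GGGG", s3 = "ACDE"))
  idx1 <- build_block_index(b1)
  w <- word_id("ACD")
  a <- idx1$entry_start[w + 1L] + 1L
  expect_equal(idx1$delta[a], 0L)
  expect_equal(idx1$count[a], 2L)
  pos <- index_positions(idx1, "ACD")
  expect_equal(pos$subject_offset, c(0L, 0L))
  expect_equal(sort(pos$seq_id), sort(match(c("s1", "s3"), b1$accession) - 1L))

  # conservation oracle over random blocks
  set.seed(61)
  b2 <- make_block(random_db_strings(40, 10, 80))
  idx2 <- build_block_index(b2)
  flat <- decode_block_flat(idx2)
  ref <- basic_flat(b2)
  expect_identical(flat$word, ref$word)
  expect_identical(flat$seq_id, ref$seq_id)
  expect_identical(flat$subject_offset, ref$subject_offset)
})

test_that("index files round-trip and re-serialize byte-identically", {
  set.seed(67)
  b <- make_block(random_db_strings(60, 10, 80))
  idx <- build_block_index(b)
  f <- withr::local_tempfile()
  save_index(idx, f)
  idx2 <- load_index(f)
  expect_equal(idx2[order(names(idx2))], idx[order(names(idx))],
               ignore_attr = TRUE)
  f2 <- withr::local_tempfile()
  save_index(idx2, f2)
  expect_identical(readBin(f, "raw", file.size(f) + 1),
                   readBin(f2, "raw", file.size(f2) + 1))
  # rebuilding from the same inputs gives a byte-identical file
  set.seed(67)
  idx3 <- build_block_index(make_block(random_db_strings(60, 10, 80)))
  f3 <- withr::local_tempfile()
  save_index(idx3, f3)
  expect_identical(readBin(f, "raw", file.size(f) + 1),
                   readBin(f3, "raw", file.size(f3) + 1))
})

test_that("index loader rejects corrupt files", {
  b <- make_block(c(a = "MKVLITGAARND"))
  idx <- build_block_index(b)
  f <- withr::local_tempfile()
  save_index(idx, f)
  raw <- readBin(f, "raw", file.size(f))
  f2 <- withr::local_tempfile()
  writeBin(raw[1:16], f2)
  expect_error(load_index(f2), "truncated")
  raw2 <- raw; raw2[2] <- as.raw(0)
  writeBin(raw2, f2)
  expect_error(load_index(f2), "magic")
  raw3 <- raw; raw3[5] <- as.raw(99)
  writeBin(raw3, f2)
  expect_error(load_index(f2), "version")
})
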