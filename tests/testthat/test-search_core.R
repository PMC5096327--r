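# brute-force hit enumeration: all (query word, subject word) matches with
# word score >= T or exact equality
brute_hits <- function(qcodes, block, T, m, W = 3L) {
  out <- list()
  for (si in seq_along(block$seqs)) {
    s <- block$seqs[[si]]
    if (length(s) < W) next
    for (o in 0:(length(s) - W)) {
      wc <- s[(o + 1):(o + W)]
      if (any(wc >= 20L)) next
      for (p in 0:(length(qcodes) - W)) {
        qc <- qcodes[(p + 1):(p + W)]
        if (any(qc >= 20L)) next
        sc <- sum(m[cbind(qc + 1L, wc + 1L)])
        if (sc >= T || all(qc == wc))
          out[[length(out) + 1L]] <- c(si - 1L, o, o - p)
      }
    }
  }
  if (!length(out))
    return(tibble::tibble(seq_id = integer(), subject_offset = integer(),
                          diagonal = integer()))
  mt <- do.call(rbind, out)
  tibble::tibble(seq_id = mt[, 1], subject_offset = mt[, 2],
                 diagonal = mt[, 3])
}

test_that("hit detection equals a quadratic scan of word matches", {
  p <- search_params()
  # no indexable word in the query
  b <- make_block(c(a = "ARNDCQEG"))
  idx <- build_block_index(b)
  bins0 <- detect_hits("XXXXX", idx, p)
  expect_equal(nrow(bins0), 0L)

  # exact self-match with neighbors disabled
  bT <- make_block(c(a = "ARN"))
  idxT <- build_block_index(bT, T = Inf)
  binsT <- detect_hits("ARN", idxT, search_params(T = Inf))
  expect_equal(nrow(binsT), 1L)
  expect_equal(binsT$diagonal, 0L)
  expect_equal(binsT$subject_offset, 0L)

  # random query/block multiset equality
  set.seed(71)
  m <- substitution_matrix("BLOSUM62")
  for (i in 1:3) {
    b2 <- make_block(random_db_strings(12, 15, 50))
    idx2 <- build_block_index(b2)
    q <- as.integer(encode_residues(random_protein(40)))
    bins <- detect_hits(q, idx2, p)
    expect_same_rows(bins[, c("seq_id", "subject_offset", "diagonal")],
                     brute_hits(q, b2, p$T, m))
    # hits within a first-level bin arrive in non-decreasing offset order
    expect_true(all(unlist(tapply(bins$subject_offset, bins$diagonal,
                                  function(x) diff(x) >= 0))))
  }
})

test_that("the two-hit filter matches the last-hit-array oracle", {
  p <- search_params(window = 40L, overlap = 3L)
  # a single hit per (sequence, diagonal) triggers nothing
  b <- make_block(c(a = "ARNDCQEGHI"))
  idx <- build_block_index(b, T = Inf)
  bins <- detect_hits("ARNWWWCQEG", idx, search_params(T = Inf))
  expect_gt(nrow(bins), 0L)
  prs <- bin_and_filter(bins, search_params(T = Inf))
  expect_equal(nrow(prs), 0L)  # no same-diagonal pair at distance >= overlap

  # two word clusters 10 apart on one diagonal emit exactly one pair:
  # within a cluster distances are 1 (< overlap), across clusters 8
  q2 <- "ARNDCXXXXXARNDC"
  b2 <- make_block(stats::setNames(q2, "dup"))
  idx2 <- build_block_index(b2, T = Inf)
  p2 <- search_params(T = Inf, window = 40L, overlap = 3L)
  bins2 <- detect_hits(q2, idx2, p2)
  prs2 <- bin_and_filter(bins2, p2)
  expect_equal(nrow(prs2), 1L)
  expect_equal(prs2$diagonal, 0L)
  expect_equal(prs2$subject_offset, 10L)
  # a window below the cluster spacing suppresses the pair
  prs2b <- bin_and_filter(bins2, search_params(T = Inf, window = 8L,
                                               overlap = 3L))
  expect_equal(nrow(prs2b), 0L)

  # fuzzed equivalence with the classical per-subject scan
  set.seed(73)
  for (i in 1:5) {
    strs <- random_db_strings(10, 20, 60)
    db <- sort_database(protein_db(strs))
    dbx <- index_database(db, 1e9)
    q <- random_protein(50)
    bins3 <- detect_hits(q, dbx$indexes[[1]], search_params())
    prs3 <- bin_and_filter(bins3, search_params())
    sc <- naive_two_hit_scan(q, db, search_params())
    expect_same_rows(prs3, sc$pairs)
  }
})

test_that("ungapped extension is an X-drop walk along the diagonal", {
  p <- search_params()
  s <- "MKVLITGAARNDWYV"
  hsp <- ungapped_extend(s, s, list(subject_offset = 5L, diagonal = 0L), p)
  m <- substitution_matrix("BLOSUM62")
  codes <- as.integer(encode_residues(s))
  self_score <- sum(diag(m[codes + 1L, codes + 1L]))
  expect_equal(hsp$score, self_score)
  expect_equal(c(hsp$q_start, hsp$q_end), c(0L, nchar(s)))

  # all-mismatch flanks stop extension at the seeded word
  q2 <- "WWWWWARNDCWWWWW"
  s2 <- "PPPPPARNDCPPPPP"
  hsp2 <- ungapped_extend(q2, s2, list(subject_offset = 5L, diagonal = 0L),
                          search_params(ungapped_cutoff = 1L))
  expect_equal(c(hsp2$q_start, hsp2$q_end), c(5L, 10L))

  # bounded by (and with infinite X-drop equal to) the best diagonal
  # segment containing the seed word
  set.seed(79)
  m <- substitution_matrix("BLOSUM62")
  for (i in 1:20) {
    q <- as.integer(encode_residues(random_protein(60)))
    s <- as.integer(encode_residues(random_protein(60)))
    pos <- sample(0:(60 - 3), 1)
    sc <- m[cbind(q + 1L, s + 1L)]  # same-diagonal per-position scores
    # exhaustive best segment [a, b] containing the word [pos, pos+2]
    best <- -Inf
    for (a in 0:pos) for (b in (pos + 2):59)
      best <- max(best, sum(sc[(a + 1):(b + 1)]))
    pinf <- search_params(xdrop_ungapped_bits = Inf, ungapped_cutoff = -1e9,
                          gap_trigger = -1e9)
    h <- ungapped_extend(q, s, list(subject_offset = pos, diagonal = 0L),
                         pinf)
    expect_equal(h$score, best)
    h7 <- ungapped_extend(q, s, list(subject_offset = pos, diagonal = 0L),
                          search_params(ungapped_cutoff = -1e9))
    expect_lte(h7$score, best)
  }
})

test_that("gapped extension reaches the local optimum through the seed", {
  p <- search_params(xdrop_gapped_bits = Inf)
  # exact duplicates align end to end without gaps
  s <- random_protein(80)
  hsp <- ungapped_extend(s, s, list(subject_offset = 10L, diagonal = 0L), p)
  g <- gapped_extend(s, s, hsp, p)
  expect_equal(g$identities, 80L)
  expect_equal(g$gaps, 0L)
  expect_equal(g$ops, strrep("M", 80))

  # a planted 2-residue insertion appears as one gap of length 2
  left <- "MKVLITGAARNDMKVLITGA"
  right <- "WYVHEQKLMNPQWYVHEQKL"
  q2 <- paste0(left, right)
  s2 <- paste0(left, "GG", right)
  hsp2 <- ungapped_extend(q2, s2, list(subject_offset = 2L, diagonal = 0L), p)
  g2 <- gapped_extend(q2, s2, hsp2, p)
  expect_equal(g2$ops, paste0(strrep("M", 20), "DD", strrep("M", 20)))
  sw2 <- sw_local(q2, s2)
  expect_equal(g2$score, sw2$score)

  # random pairs seeded on the known homologous diagonal: never above
  # Smith-Waterman, and equal because the optimum traverses the seed
  set.seed(83)
  for (i in 1:15) {
    q <- random_protein(70)
    sseq <- paste0(random_protein(20), substr(q, 11, 50), random_protein(20))
    h <- ungapped_extend(q, sseq,
                         list(subject_offset = 30L, diagonal = 10L),
                         search_params(ungapped_cutoff = 1L))
    g <- gapped_extend(q, sseq, h, p)
    sw <- sw_local(q, sseq)
    expect_lte(g$score, sw$score)
    expect_equal(g$score, sw$score)
  }
})

test_that("search_block composes the stages and deduplicates", {
  p <- search_params()
  set.seed(89)
  # no homologs above the cutoff
  db0 <- sort_database(protein_db(random_db_strings(10, 30, 60)))
  dbx0 <- index_database(db0, 1e9)
  r0 <- search_block(random_protein(50), indexed_block(dbx0, 1), p)
  expect_equal(nrow(r0), 0L)

  # one planted homolog is found
  gen <- generate_database(synthetic_spec(n_sequences = 25, n_planted = 1,
                                          identity = 0.8, seed = 97))
  db <- sort_database(gen$db)
  dbx <- index_database(db, 1e9)
  qacc <- gen$truth$donor[1]
  q <- db$seqs[[match(qacc, db$meta$accession)]]
  r <- search_block(q, indexed_block(dbx, 1), p)
  expect_true(gen$truth$receiver[1] %in% r$subject)
  best <- r[r$subject == gen$truth$receiver[1], ][1, ]
  expect_lt(best$evalue, 1e-10)
  # reported spans are inside sequence bounds
  expect_true(all(r$q_end <= length(q) & r$q_start >= 0))
  # no alignment is contained in a better one of the same subject
  for (sj in unique(r$subject)) {
    rs <- r[r$subject == sj, ]
    if (nrow(rs) < 2) next
    for (i in 2:nrow(rs)) for (j in 1:(i - 1))
      expect_false(rs$q_start[i] >= rs$q_start[j] &&
                   rs$q_end[i] <= rs$q_end[j] &&
                   rs$s_start[i] >= rs$s_start[j] &&
                   rs$s_end[i] <= rs$s_end[j])
  }
})
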