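# In-code fixtures shared across test files. All randomness is seeded
# locally so tests are order-independent.

# a db_block holding the given residue strings as one block
make_block <- function(strings, block_cap = 1e9) {
  if (is.null(names(strings)))
    names(strings) <- paste0("s", seq_along(strings))
  db <- sort_database(protein_db(strings))
  partition_blocks(db, block_cap)[[1]]
}

# random residue string over the 20-letter alphabet
random_protein <- function(n) {
  paste(sample(strsplit(aa_alphabet(), "")[[1]], n, TRUE), collapse = "")
}

# a small random database as a named character vector
random_db_strings <- function(n_seqs, min_len = 30, max_len = 90) {
  lens <- sample(min_len:max_len, n_seqs, TRUE)
  stats::setNames(vapply(lens, random_protein, ""),
                  sprintf("r%03d", seq_len(n_seqs)))
}

# vectorised whole-block decode of a block_index: absolute offsets by
# per-word segmented cumsum of the deltas, positions expanded by count
decode_block_flat <- function(idx) {
  n_ent <- length(idx$delta)
  if (n_ent == 0L)
    return(list(word = integer(), seq_id = integer(),
                subject_offset = integer()))
  ent_word <- rep.int(seq_len(length(idx$entry_start) - 1L) - 1L,
                      diff(idx$entry_start))
  cs <- cumsum(idx$delta)
  first_i <- pmin(utils::head(idx$entry_start, -1L) + 1L, n_ent)
  seg_base <- cs[first_i] - idx$delta[first_i]  # cumsum before each word
  abs_off <- cs - rep.int(seg_base, diff(idx$entry_start))
  list(word = rep.int(ent_word, idx$count),
       seq_id = idx$sids,
       subject_offset = rep.int(abs_off, idx$count))
}

# sorted basic-index positions of a block as the same flat layout
basic_flat <- function(block, W = 3L) {
  widx <- sort_positions(build_basic_index(block, W))
  list(word = rep.int(seq_len(length(widx$word_start) - 1L) - 1L,
                      diff(widx$word_start)),
       seq_id = widx$seq_id,
       subject_offset = widx$offset)
}

# strip tibble attributes so frames compare on content only
plain <- function(x) {
  x <- as.data.frame(x)
  attr(x, "row.names") <- seq_len(nrow(x))
  x
}

expect_same_rows <- function(a, b) {
  a <- plain(a); b <- plain(b)
  ka <- do.call(order, a); kb <- do.call(order, b)
  expect_equal(a[ka, , drop = FALSE], b[kb, , drop = FALSE],
               ignore_attr = TRUE)
}
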