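#' Build the basic (uncompressed) index of a block
#'
#' Every overlapping W-mer whose residues are all indexable contributes one
#' position (block-local sequence id, 0-based subject offset); windows that
#' touch a masked residue are skipped. Positions are grouped by word id, in
#' (seq_id, subject_offset) scan order within each word.
#'
#' @param block A `db_block` from [partition_blocks()].
#' @param W Word length (default 3).
#' @return A `word_index`: flat position arrays with per-word start offsets.
#' @export
build_basic_index <- function(block, W = 3L) {
  stopifnot(inherits(block, "db_block"), W >= 1)
  res <- .basic_index_cpp(block$seqs, as.integer(W), .alpha_size)
  structure(list(W = as.integer(W), asize = .alpha_size,
                 word_start = res$word_start, seq_id = res$seq_id,
                 offset = res$offset, sorted = FALSE),
            class = "word_index")
}

#' @export
print.word_index <- function(x, ...) {
  cat(sprintf("<word_index> W=%d, %d positions over %d words%s\n", x$W,
              length(x$offset), sum(diff(x$word_start) > 0L),
              if (x$sorted) ", sorted" else ""))
  invisible(x)
}

#' Sort index positions by subject offset
#'
#' Per word, positions are reordered by (subject offset, sequence id),
#' stably. Sorting groups repeated subject offsets together (enabling the
#' merge compression) and makes posting-list traversal emit hits in
#' subject-offset order, which keeps first-level binning writes sequential.
#'
#' @param index A `word_index` from [build_basic_index()].
#' @return The sorted `word_index`.
#' @export
sort_positions <- function(index) {
  stopifnot(inherits(index, "word_index"))
  res <- .sort_index_cpp(index$word_start, index$seq_id, index$offset)
  index$seq_id <- res$seq_id
  index$offset <- res$offset
  index$sorted <- TRUE
  index
}

#' Positions of one word as a tibble
#'
#' @param index A `word_index`.
#' @param word Word string or 0-based word id.
#' @return Tibble with `seq_id`, `subject_offset`.
#' @export
word_positions <- function(index, word) {
  if (is.character(word)) word <- word_id(word)
  stopifnot(!is.na(word), word >= 0, word < length(index$word_start) - 1L)
  a <- index$word_start[word + 1L] + 1L
  b <- index$word_start[word + 2L]
  if (b < a) return(tibble::tibble(seq_id = integer(), subject_offset = integer()))
  tibble::tibble(seq_id = index$seq_id[a:b],
                 subject_offset = index$offset[a:b])
}

#' Compress the sorted positions of one word
#'
#' Consecutive positions sharing a subject offset are merged into one entry
#' holding the offset once and all sequence ids; offsets are then stored as
#' 8-bit increments from the previous entry's absolute offset (the first
#' entry's increment is taken from absolute offset 0). Entries whose
#' increment or count would exceed 255 are split by [split_overflow()].
#'
#' @param positions Data frame with `seq_id` and `subject_offset`, sorted by
#'   (subject_offset, seq_id).
#' @return Tibble of compressed entries: `delta`, `count`, and a `seq_ids`
#'   list-column.
#' @export
compress_positions <- function(positions) {
  off <- as.integer(positions$subject_offset)
  sid <- as.integer(positions$seq_id)
  if (is.unsorted(off)) stop("positions must be sorted by subject offset")
  if (length(off) == 0L)
    return(tibble::tibble(delta = integer(), count = integer(),
                          seq_ids = list()))
  r <- rle(off)
  values <- r$values
  counts <- r$lengths
  deltas <- diff(c(0L, values))
  ends <- cumsum(counts)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out_d <- list(); out_c <- list(); out_s <- list()
  for (i in seq_along(values)) {
    ids <- sid[starts[i]:ends[i]]
    if (deltas[i] <= 255L && counts[i] <= 255L) {
      out_d[[i]] <- deltas[i]; out_c[[i]] <- counts[i]; out_s[[i]] <- list(ids)
    } else {
      sp <- split_overflow(deltas[i], counts[i], ids)
      out_d[[i]] <- sp$delta; out_c[[i]] <- sp$count; out_s[[i]] <- sp$seq_ids
    }
  }
  tibble::tibble(delta = unlist(out_d), count = unlist(out_c),
                 seq_ids = do.call(c, out_s))
}

#' Split an overflowing compressed entry
#'
#' The increment and count fields are 8-bit, so an entry whose increment
#' exceeds 255 is preceded by padding entries carrying increment 255 and
#' count 0, and an entry with more than 255 positions is emitted as maximal
#' 255-count entries (increment on the first) followed by the remainder with
#' increment 0. Decoding recovers exactly the original offset and id list.
#'
#' @param delta Incremental subject offset (>= 0).
#' @param count Number of positions (= `length(seq_ids)`).
#' @param seq_ids Block-local sequence ids at this offset.
#' @return Tibble of entries as in [compress_positions()].
#' @export
split_overflow <- function(delta, count, seq_ids) {
  stopifnot(delta >= 0, count == length(seq_ids))
  d <- as.integer(delta)
  out_d <- integer(); out_c <- integer(); out_s <- list()
  while (d > 255L) {
    out_d <- c(out_d, 255L); out_c <- c(out_c, 0L)
    out_s <- c(out_s, list(integer()))
    d <- d - 255L
  }
  remaining <- as.integer(seq_ids)
  first <- TRUE
  repeat {
    take <- min(length(remaining), 255L)
    out_d <- c(out_d, if (first) d else 0L)
    out_c <- c(out_c, take)
    out_s <- c(out_s, list(remaining[seq_len(take)]))
    remaining <- remaining[-seq_len(take)]
    first <- FALSE
    if (length(remaining) == 0L) break
  }
  tibble::tibble(delta = out_d, count = out_c, seq_ids = out_s)
}

#' Decode compressed entries back to positions
#'
#' Exact inverse of [compress_positions()] including overflow splits.
#'
#' @param entries Tibble of entries (`delta`, `count`, `seq_ids`).
#' @return Tibble with `seq_id`, `subject_offset`, sorted by
#'   (subject_offset, seq_id).
#' @export
decode_positions <- function(entries) {
  if (nrow(entries) == 0L)
    return(tibble::tibble(seq_id = integer(), subject_offset = integer()))
  bad <- entries$count != lengths(entries$seq_ids)
  if (any(bad))
    stop("entry ", which(bad)[1], ": count does not match seq_ids length")
  if (any(entries$delta > 255L | entries$delta < 0L |
          entries$count > 255L | entries$count < 0L))
    stop("entry fields must be in 0..255")
  abs_off <- cumsum(entries$delta)
  tibble::tibble(
    seq_id = as.integer(unlist(entries$seq_ids)),
    subject_offset = rep(as.integer(abs_off), entries$count)
  )
}

# ------------------------------------------------------------- neighbor words

.neighbor_cache_key <- function(matrix, T, W) {
  nm <- attr(matrix, "matrix_name")
  if (is.null(nm)) nm <- paste0("custom", sum(matrix * seq_along(matrix)))
  paste0("nb_", nm, "_", T, "_", W)
}

.neighbor_table <- function(matrix, T, W = 3L) {
  key <- .neighbor_cache_key(matrix, T, W)
  if (!is.null(.dbb_cache[[key]])) return(.dbb_cache[[key]])
  Tc <- max(min(T, .Machine$integer.max / 2), -.Machine$integer.max / 2)
  res <- .neighbors_all_cpp(matrix[seq_len(.alpha_size), seq_len(.alpha_size)],
                            Tc, as.integer(W), .alpha_size)
  .dbb_cache[[key]] <- res
  res
}

#' Neighboring words of a word
#'
#' All words w' different from w whose ungapped word score against w (the sum
#' of per-position substitution scores) reaches the neighbor threshold T.
#' Protein search seeds on these similar words, not only on exact matches;
#' the index stores each word's neighbor list as offsets so neighbor
#' positions are never materialised.
#'
#' @param word Word string or 0-based word id.
#' @param matrix Scoring matrix (name or matrix, see [substitution_matrix()]).
#' @param T Neighbor threshold (default 11, the usual BLASTP setting).
#' @param W Word length (default 3).
#' @return Integer vector of 0-based neighbor word ids, ascending.
#' @export
compute_neighbor_words <- function(word, matrix = "BLOSUM62", T = 11, W = 3L) {
  if (is.character(word)) word <- word_id(word)
  stopifnot(!is.na(word))
  m <- substitution_matrix(matrix)
  nb <- .neighbor_table(m, T, W)
  a <- nb$nb_start[word + 1L] + 1L
  b <- nb$nb_start[word + 2L]
  if (b < a) integer() else nb$nb[a:b]
}

# ---------------------------------------------------------------- block index

#' Build the compressed index of one database block
#'
#' Pipeline: basic indexing, position sorting, merge + increment compression,
#' and the lookup table with neighbor-word offsets. The result is
#' self-describing and serialisable with [save_index()].
#'
#' @param block A `db_block`.
#' @param W Word length (default 3).
#' @param T Neighbor threshold (default 11).
#' @param matrix Scoring matrix name or matrix (default BLOSUM62).
#' @return A `block_index`.
#' @export
build_block_index <- function(block, W = 3L, T = 11, matrix = "BLOSUM62") {
  widx <- sort_positions(build_basic_index(block, W))
  comp <- .compress_block_cpp(widx$word_start, widx$seq_id, widx$offset)
  m <- substitution_matrix(matrix)
  nb <- .neighbor_table(m, T, W)
  idx <- structure(list(
    block_id = block$block_id,
    W = as.integer(W), asize = .alpha_size, T = T,
    matrix_name = attr(m, "matrix_name") %||% "custom",
    n_seqs = length(block$seqs),
    letters = block$letters,
    max_len = block$max_seq_length,
    entry_start = comp$entry_start,
    delta = comp$delta,
    count = comp$count,
    sid_start = comp$sid_start,
    sids = comp$sids,
    nb_start = nb$nb_start,
    nb = nb$nb
  ), class = "block_index")
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.block_index <- function(x, ...) {
  cat(sprintf(
    "<block_index #%d> W=%d T=%s %s; %d seqs, %d letters, %d entries\n",
    x$block_id, x$W, format(x$T), x$matrix_name, x$n_seqs, x$letters,
    length(x$delta)))
  invisible(x)
}

#' Decode the positions of one word from a block index
#'
#' @param index A `block_index`.
#' @param word Word string or 0-based id.
#' @return Tibble with `seq_id`, `subject_offset` (sorted).
#' @export
index_positions <- function(index, word) {
  if (is.character(word)) word <- word_id(word)
  a <- index$entry_start[word + 1L] + 1L
  b <- index$entry_start[word + 2L]
  if (b < a)
    return(tibble::tibble(seq_id = integer(), subject_offset = integer()))
  rng <- a:b
  sid_lists <- lapply(rng, function(e) {
    s <- index$sid_start[e] + 1L
    t <- index$sid_start[e + 1L]
    if (t < s) integer() else index$sids[s:t]
  })
  decode_positions(tibble::tibble(delta = index$delta[rng],
                                  count = index$count[rng],
                                  seq_ids = sid_lists))
}

# ------------------------------------------------------------------- file i/o

.IDX_MAGIC <- charToRaw("DBPI")
.IDX_VERSION <- 1L

.write_ivec <- function(con, v) {
  writeBin(length(v), con, size = 4L, endian = "little")
  writeBin(as.integer(v), con, size = 4L, endian = "little")
}

.read_ivec <- function(con) {
  n <- .read_ints(con, 1L)
  .read_ints(con, n)
}

#' Serialize a block index
#'
#' Fixed-width little-endian layout with a magic/version/parameter header;
#' the 8-bit increment and count fields are stored as single bytes. The same
#' inputs always serialise to byte-identical files.
#'
#' @param index A `block_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "block_index"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.IDX_MAGIC, con)
  writeBin(.IDX_VERSION, con, size = 4L, endian = "little")
  writeBin(as.integer(c(index$W, index$asize)), con, size = 4L,
           endian = "little")
  writeBin(as.double(index$T), con, size = 8L, endian = "little")
  .write_string(con, index$matrix_name)
  writeBin(as.integer(c(index$block_id, index$n_seqs, index$letters,
                        index$max_len)), con, size = 4L, endian = "little")
  .write_ivec(con, index$entry_start)
  writeBin(length(index$delta), con, size = 4L, endian = "little")
  writeBin(as.raw(index$delta), con)
  writeBin(as.raw(index$count), con)
  .write_ivec(con, index$sid_start)
  .write_ivec(con, index$sids)
  .write_ivec(con, index$nb_start)
  .write_ivec(con, index$nb)
  invisible(path)
}

#' Load a block index
#'
#' @param path Path written by [save_index()].
#' @return A `block_index`, identical to the one saved.
#' @export
load_index <- function(path) {
  stopifnot(file.exists(path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (length(magic) != 4L || !identical(magic, .IDX_MAGIC))
    stop("bad magic in ", path, ": expected ", rawToChar(.IDX_MAGIC),
         ", found 0x", paste(as.character(magic), collapse = ""))
  ver <- .read_ints(con, 1L)
  if (ver != .IDX_VERSION)
    stop("unsupported index version: expected ", .IDX_VERSION,
         ", found ", ver)
  wa <- .read_ints(con, 2L)
  T <- readBin(con, "double", 1L, size = 8L, endian = "little")
  if (length(T) != 1L) stop("truncated file")
  matrix_name <- .read_string(con)
  hdr <- .read_ints(con, 4L)
  entry_start <- .read_ivec(con)
  n_ent <- .read_ints(con, 1L)
  delta <- readBin(con, "raw", n_ent)
  count <- readBin(con, "raw", n_ent)
  if (length(delta) != n_ent || length(count) != n_ent) stop("truncated file")
  structure(list(
    block_id = hdr[1], W = wa[1], asize = wa[2], T = T,
    matrix_name = matrix_name, n_seqs = hdr[2], letters = hdr[3],
    max_len = hdr[4], entry_start = entry_start,
    delta = as.integer(delta), count = as.integer(count),
    sid_start = .read_ivec(con), sids = .read_ivec(con),
    nb_start = .read_ivec(con), nb = .read_ivec(con)
  ), class = "block_index")
}
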