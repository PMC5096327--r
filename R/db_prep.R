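#' Read a protein FASTA file
#'
#' Records are parsed with Biostrings; residues are uppercased and encoded
#' over the package alphabet (see [encode_residues()]). Characters outside
#' the alphabet are mapped to the mask code with one warning giving the total
#' count. The accession is the header token before the first whitespace; the
#' remainder is the description.
#'
#' @param path Path to a FASTA file (multi-line sequences allowed).
#' @return A `protein_db` object: a `meta` tibble (accession, description,
#'   length) plus the encoded sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  head_lines <- readLines(path, n = 100L, warn = FALSE)
  nonblank <- which(nzchar(trimws(head_lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  first <- nonblank[[1]]
  if (!startsWith(trimws(head_lines[[first]]), ">"))
    stop("malformed FASTA: sequence data before any header at line ", first,
         " of ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  strings <- as.character(set)
  if (any(nchar(strings) == 0L))
    stop("empty sequence for record: ",
         accession[which(nchar(strings) == 0L)[1]])
  seqs <- lapply(strings, encode_residues)
  n_unknown <- sum(vapply(seqs, function(s) attr(s, "n_unknown"), 0L))
  if (n_unknown > 0L)
    warning(n_unknown, " residue(s) outside the alphabet were masked",
            call. = FALSE)
  seqs <- lapply(seqs, function(s) { attributes(s) <- NULL; s })
  new_protein_db(accession, description, seqs)
}

#' Construct a protein database from in-memory sequences
#'
#' @param sequences Named character vector of residue strings (names are
#'   accessions, optionally "acc description").
#' @return A `protein_db`.
#' @export
protein_db <- function(sequences) {
  stopifnot(is.character(sequences), length(sequences) >= 1L,
            !is.null(names(sequences)))
  accession <- sub("\\s.*$", "", names(sequences))
  description <- ifelse(grepl("\\s", names(sequences)),
                        sub("^\\S+\\s+", "", names(sequences)), "")
  seqs <- lapply(unname(sequences), function(x) {
    s <- encode_residues(x); attributes(s) <- NULL; s
  })
  if (any(lengths(seqs) == 0L)) stop("empty sequence")
  new_protein_db(accession, description, seqs)
}

new_protein_db <- function(accession, description, seqs, sorted = FALSE,
                           sorted_to_orig = NULL) {
  db <- list(
    meta = tibble::tibble(accession = unname(accession),
                          description = unname(description),
                          length = unname(lengths(seqs))),
    seqs = unname(seqs),
    sorted = sorted,
    sorted_to_orig = sorted_to_orig
  )
  class(db) <- if (sorted) c("sorted_db", "protein_db") else "protein_db"
  db
}

#' @export
print.protein_db <- function(x, ...) {
  cat(sprintf("<%s> %d sequences, %d letters%s\n",
              class(x)[1], nrow(x$meta), sum(x$meta$length),
              if (isTRUE(x$sorted)) ", length-sorted" else ""))
  print(utils::head(x$meta, 5))
  invisible(x)
}

#' @export
length.protein_db <- function(x) nrow(x$meta)

#' Sort a database by sequence length
#'
#' Sequences are ordered by non-decreasing length, ties broken by original
#' input order (stable), so builds are reproducible. The original order is
#' retained in the `sorted_to_orig` map so reports can use original
#' accessions and positions.
#'
#' @param db A `protein_db`.
#' @return A `sorted_db` (also a `protein_db`).
#' @export
sort_database <- function(db) {
  stopifnot(inherits(db, "protein_db"))
  ord <- order(db$meta$length, method = "radix")  # radix order is stable
  new_protein_db(db$meta$accession[ord], db$meta$description[ord],
                 db$seqs[ord], sorted = TRUE, sorted_to_orig = ord)
}

#' Partition a sorted database into letter-capped blocks
#'
#' Blocks are filled greedily in sorted order; a sequence that would push a
#' block past `block_cap` letters starts the next block, so no sequence ever
#' spans two blocks. A single sequence longer than the cap occupies a block
#' of its own. Small blocks keep block-local sequence ids and subject offsets
#' narrow (see [seqid_bit_width()]) and let an index block fit in cache.
#'
#' @param db A `sorted_db` from [sort_database()].
#' @param block_cap Maximum letters per block (default 131072, i.e. 128 K).
#' @return List of `db_block` objects.
#' @export
partition_blocks <- function(db, block_cap = 131072L) {
  stopifnot(inherits(db, "sorted_db"), block_cap >= 1)
  n <- nrow(db$meta)
  lens <- db$meta$length
  blocks <- list()
  start <- 1L
  while (start <= n) {
    letters <- 0L
    end <- start - 1L
    while (end < n && (letters + lens[end + 1L] <= block_cap || end < start)) {
      end <- end + 1L
      letters <- letters + lens[end]
    }
    idx <- start:end
    b <- list(
      block_id = length(blocks) + 1L,
      seqs = db$seqs[idx],
      accession = db$meta$accession[idx],
      lengths = lens[idx],
      letters = letters,
      max_seq_length = max(lens[idx]),
      local_to_global = idx
    )
    class(b) <- "db_block"
    blocks[[length(blocks) + 1L]] <- b
    start <- end + 1L
  }
  blocks
}

#' @export
print.db_block <- function(x, ...) {
  cat(sprintf("<db_block #%d> %d sequences, %d letters, max length %d\n",
              x$block_id, length(x$seqs), x$letters, x$max_seq_length))
  invisible(x)
}

# ---------------------------------------------------------------- binary file

.DB_MAGIC <- charToRaw("DBPF")
.DB_VERSION <- 1L

.write_string <- function(con, x) {
  r <- charToRaw(enc2utf8(x))
  writeBin(length(r), con, size = 4L, endian = "little")
  writeBin(r, con)
}

.read_string <- function(con) {
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(n) != 1L) stop("truncated file")
  rawToChar(readBin(con, "raw", n))
}

.read_ints <- function(con, n) {
  v <- readBin(con, "integer", n, size = 4L, endian = "little")
  if (length(v) != n) stop("truncated file")
  v
}

#' Write a formatted database file
#'
#' Binary layout: magic/version header, alphabet string, sorted flag, per-
#' sequence metadata and lengths, the sorted-to-original id map when the
#' database is sorted, and the packed 8-bit residue codes. This is the
#' on-disk product of the `formatdb`/`sortdb` stages.
#'
#' @param db A `protein_db` or `sorted_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_formatted_db <- function(db, path) {
  stopifnot(inherits(db, "protein_db"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.DB_MAGIC, con)
  writeBin(.DB_VERSION, con, size = 4L, endian = "little")
  .write_string(con, aa_alphabet())
  writeBin(as.integer(isTRUE(db$sorted)), con, size = 4L, endian = "little")
  n <- nrow(db$meta)
  writeBin(n, con, size = 4L, endian = "little")
  writeBin(as.integer(db$meta$length), con, size = 4L, endian = "little")
  for (i in seq_len(n)) {
    .write_string(con, db$meta$accession[i])
    .write_string(con, db$meta$description[i])
  }
  if (isTRUE(db$sorted))
    writeBin(as.integer(db$sorted_to_orig), con, size = 4L, endian = "little")
  writeBin(as.raw(unlist(db$seqs, use.names = FALSE)), con)
  invisible(path)
}

#' Read a formatted database file
#'
#' @param path Path written by [write_formatted_db()].
#' @return A `protein_db` (or `sorted_db` if it was written sorted).
#' @export
read_formatted_db <- function(path) {
  stopifnot(file.exists(path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(magic, .DB_MAGIC))
    stop("bad magic in ", path, ": expected ", rawToChar(.DB_MAGIC),
         ", found 0x", paste(as.character(magic), collapse = ""))
  ver <- .read_ints(con, 1L)
  if (ver != .DB_VERSION)
    stop("unsupported database file version: expected ", .DB_VERSION,
         ", found ", ver)
  alpha <- .read_string(con)
  if (alpha != aa_alphabet()) stop("alphabet mismatch in ", path)
  sorted <- .read_ints(con, 1L) == 1L
  n <- .read_ints(con, 1L)
  lens <- .read_ints(con, n)
  accession <- character(n); description <- character(n)
  for (i in seq_len(n)) {
    accession[i] <- .read_string(con)
    description[i] <- .read_string(con)
  }
  map <- if (sorted) .read_ints(con, n) else NULL
  codes <- readBin(con, "raw", sum(lens))
  if (length(codes) != sum(lens)) stop("truncated file")
  codes <- as.integer(codes)
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  seqs <- lapply(seq_len(n), function(i) codes[starts[i]:ends[i]])
  new_protein_db(accession, description, seqs, sorted = sorted,
                 sorted_to_orig = map)
}
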