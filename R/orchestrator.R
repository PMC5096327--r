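#' Index a database for searching
#'
#' Sorts the database by length (if needed), partitions it into letter-capped
#' blocks, and builds the compressed index of every block. The default block
#' size of 128 K letters keeps one index block around the size of a CPU L2
#' cache; single-threaded runs may raise it.
#'
#' @param db A `protein_db` (sorted or not).
#' @param block_cap Letters per block (default 131072).
#' @param params A `search_params` (supplies W, T, matrix).
#' @return A `db_index` holding the sorted database, its blocks, one
#'   `block_index` per block, and whole-database statistics.
#' @export
index_database <- function(db, block_cap = 131072L,
                           params = search_params()) {
  stopifnot(inherits(db, "protein_db"))
  if (!inherits(db, "sorted_db")) db <- sort_database(db)
  blocks <- partition_blocks(db, block_cap)
  indexes <- lapply(blocks, build_block_index, W = params$W, T = params$T,
                    matrix = params$matrix)
  structure(list(db = db, blocks = blocks, indexes = indexes,
                 block_cap = as.integer(block_cap),
                 db_letters = sum(db$meta$length),
                 db_seqs = nrow(db$meta)),
            class = "db_index")
}

#' @export
print.db_index <- function(x, ...) {
  cat(sprintf("<db_index> %d sequences, %d letters, %d blocks (cap %d)\n",
              x$db_seqs, x$db_letters, length(x$blocks), x$block_cap))
  invisible(x)
}

#' One indexed block of a `db_index`
#'
#' @param dbx A `db_index`.
#' @param i Block number.
#' @return An `indexed_block` (block data plus its `block_index`), the unit
#'   [search_block()] operates on.
#' @export
indexed_block <- function(dbx, i) {
  stopifnot(inherits(dbx, "db_index"), i >= 1, i <= length(dbx$blocks))
  structure(list(block = dbx$blocks[[i]], index = dbx$indexes[[i]]),
            class = "indexed_block")
}

.index_checksum <- function(dbx) {
  acc <- 0
  for (ix in dbx$indexes)
    acc <- (acc + length(ix$delta) * 31 + sum(ix$delta) + sum(ix$count) +
              ix$letters) %% 2147483647
  sprintf("%x", acc)
}

.normalize_queries <- function(queries) {
  if (inherits(queries, "protein_db")) {
    list(accession = queries$meta$accession, codes = queries$seqs)
  } else if (is.character(queries)) {
    if (is.null(names(queries)))
      names(queries) <- paste0("query", seq_along(queries))
    list(accession = sub("\\s.*$", "", names(queries)),
         codes = lapply(unname(queries), function(x) {
           s <- encode_residues(x); attributes(s) <- NULL; s
         }))
  } else stop("queries must be a named character vector or a protein_db")
}

#' Batch search with block-wise scheduling
#'
#' The outer loop walks index blocks; the inner loop (parallelisable across
#' `workers`) runs hit detection, binning/filtering, and ungapped extension
#' for every query against the current block, so all workers share one index
#' block at a time. Per-(query, block) HSP partials are merged, gapped
#' extension with traceback runs on the merged survivors against the
#' whole-database search space, and results are ranked deterministically.
#' Output is independent of `workers` and of the block partitioning.
#'
#' @param queries Named character vector of residue strings, or a
#'   `protein_db`. Queries shorter than W yield a warning and no hits.
#' @param dbx A `db_index` from [index_database()].
#' @param params A `search_params`.
#' @param workers Number of worker processes for the inner query loop.
#' @return A `batch_result`: `hits` tibble (query, subject, scores, E-value,
#'   1-based inclusive coordinates, alignment statistics, edit string) plus
#'   run metadata.
#' @export
run_batch <- function(queries, dbx, params = search_params(), workers = 1L) {
  stopifnot(inherits(dbx, "db_index"), workers >= 1)
  t0 <- proc.time()[["elapsed"]]
  qs <- .normalize_queries(queries)
  n_q <- length(qs$codes)
  stopifnot(n_q >= 1, length(dbx$blocks) >= 1)
  fin <- .finalize_params(params)
  short <- vapply(qs$codes, length, 0L) < fin$W
  if (any(short))
    warning("queries shorter than the word length return no hits: ",
            paste(qs$accession[short], collapse = ", "), call. = FALSE)
  apply_fun <- if (workers > 1L && .Platform$OS.type == "unix") {
    function(x, f) parallel::mclapply(x, f, mc.cores = workers,
                                      mc.preschedule = TRUE)
  } else {
    function(x, f) lapply(x, f)
  }
  hsp_parts <- vector("list", n_q)  # per query: list of HSP tibbles
  for (b in seq_along(dbx$blocks)) {
    block <- dbx$blocks[[b]]
    index <- dbx$indexes[[b]]
    part <- apply_fun(seq_len(n_q), function(qi) {
      codes <- qs$codes[[qi]]
      if (length(codes) < fin$W) return(NULL)
      bins <- detect_hits(codes, index, params)
      pairs <- bin_and_filter(bins, params)
      hsps <- .ungapped_stage(codes, block$seqs, pairs, fin)
      if (nrow(hsps) == 0L) return(NULL)
      hsps$id <- block$local_to_global[hsps$seq_id + 1L]  # 1-based global
      hsps
    })
    for (qi in seq_len(n_q))
      if (!is.null(part[[qi]]))
        hsp_parts[[qi]] <- c(hsp_parts[[qi]], list(part[[qi]]))
  }
  db <- dbx$db
  out <- vector("list", n_q)
  for (qi in seq_len(n_q)) {
    hsps <- if (length(hsp_parts[[qi]])) {
      unique(do.call(rbind, hsp_parts[[qi]]))
    } else {
      tibble::tibble(seq_id = integer(), q_start = integer(),
                     q_end = integer(), s_start = integer(),
                     s_end = integer(), score = integer(), id = integer())
    }
    al <- .gapped_stage(qs$codes[[qi]], hsps,
                        get_seq = function(id) db$seqs[[id]],
                        get_acc = function(id) db$meta$accession[[id]],
                        fin, dbx$db_letters, dbx$db_seqs)
    al$seq_id <- NULL
    al <- utils::head(al, fin$max_reported)
    if (nrow(al))
      al <- tibble::tibble(query = qs$accession[[qi]], al)
    out[[qi]] <- al
  }
  out <- out[vapply(out, nrow, 0L) > 0L]
  hits <- if (length(out)) do.call(rbind, out) else tibble::tibble(
    query = character(), subject = character(), raw_score = integer(),
    bit_score = numeric(), evalue = numeric(), q_start = integer(),
    q_end = integer(), s_start = integer(), s_end = integer(),
    length = integer(), identities = integer(), positives = integer(),
    gaps = integer(), ops = character())
  structure(list(hits = hits, params = params,
                 metadata = list(db_letters = dbx$db_letters,
                                 db_seqs = dbx$db_seqs,
                                 n_blocks = length(dbx$blocks),
                                 block_cap = dbx$block_cap,
                                 index_checksum = .index_checksum(dbx),
                                 n_queries = n_q,
                                 elapsed = proc.time()[["elapsed"]] - t0)),
            class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("<batch_result> %d queries, %d alignments (db: %d seqs, %d letters, %d blocks)\n",
              x$metadata$n_queries, nrow(x$hits), x$metadata$db_seqs,
              x$metadata$db_letters, x$metadata$n_blocks))
  print(x$hits)
  invisible(x)
}

#' Merge per-block alignment partials
#'
#' Resolves block-local sequence ids to global accessions through the
#' per-block id maps, concatenates, re-ranks by (E-value ascending, raw
#' score descending, accession ascending), and truncates to
#' `params$max_reported`. Because blocks partition the database, a subject
#' can only come from one block; a subject seen in two partials indicates a
#' corrupted partition and is an error, as is an unresolvable id.
#'
#' @param partials List of per-block alignment tibbles (as returned by
#'   [search_block()], with their block-local `seq_id` column).
#' @param id_maps List (same length) of character vectors mapping 0-based
#'   block-local ids to accessions.
#' @param params A `search_params`.
#' @return One ranked alignment tibble with resolved `subject`.
#' @export
merge_results <- function(partials, id_maps, params = search_params()) {
  stopifnot(is.list(partials), is.list(id_maps),
            length(partials) == length(id_maps))
  resolved <- Map(function(p, map) {
    if (nrow(p) == 0L) return(p)
    idx <- p$seq_id + 1L
    if (any(idx < 1L | idx > length(map)))
      stop("unresolvable block-local sequence id: ",
           p$seq_id[which(idx < 1L | idx > length(map))[1]])
    p$subject <- map[idx]
    p
  }, partials, id_maps)
  subj <- lapply(resolved, function(p) unique(p$subject))
  dup <- unlist(subj)[duplicated(unlist(subj))]
  if (length(dup))
    stop("duplicate subject across block partials: ", dup[1])
  out <- do.call(rbind, resolved)
  out <- out[order(out$evalue, -out$raw_score, out$subject, out$q_start,
                   out$s_start), , drop = FALSE]
  utils::head(out, params$max_reported)
}
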