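#' Smith-Waterman local alignment (reference implementation)
#'
#' Full O(mn) affine-gap local alignment in plain R, used as the optimality
#' oracle for the heuristic engine. A gap of length L costs
#' `gap_open + gap_extend * L` (the engine's convention). The best-scoring
#' cell is the earliest in row-major order among ties; one traceback is
#' returned.
#'
#' @param query,subject Residue strings or integer codes.
#' @param matrix Matrix name or 21x21 matrix.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return List: `score`, 0-based half-open `q_start`/`q_end`/`s_start`/
#'   `s_end`, and edit string `ops` (M/I/D, I consumes query only). A score
#'   of 0 returns an empty alignment.
#' @export
sw_local <- function(query, subject, matrix = "BLOSUM62", gap_open = 11L,
                     gap_extend = 1L) {
  q <- .query_codes(query); s <- .query_codes(subject)
  S <- unname(substitution_matrix(matrix))
  m <- length(q); n <- length(s)
  goe <- gap_open + gap_extend
  ge <- gap_extend
  NEG <- -1e9
  H <- matrix(0, m + 1L, n + 1L)
  E <- matrix(NEG, m + 1L, n + 1L)
  F_ <- matrix(NEG, m + 1L, n + 1L)
  dirH <- matrix(0L, m + 1L, n + 1L)  # 0 stop, 1 diag, 2 E, 3 F
  dirE <- matrix(0L, m + 1L, n + 1L)  # 1 open, 2 extend
  dirF <- matrix(0L, m + 1L, n + 1L)
  best <- 0; bi <- 0L; bj <- 0L
  qrow <- q + 1L
  for (i in seq_len(m)) {
    Si <- S[qrow[i], ]
    for (j in seq_len(n)) {
      e_open <- H[i + 1L, j] - goe
      e_ext <- E[i + 1L, j] - ge
      if (e_ext > e_open) { E[i + 1L, j + 1L] <- e_ext; dirE[i + 1L, j + 1L] <- 2L }
      else { E[i + 1L, j + 1L] <- e_open; dirE[i + 1L, j + 1L] <- 1L }
      f_open <- H[i, j + 1L] - goe
      f_ext <- F_[i, j + 1L] - ge
      if (f_ext > f_open) { F_[i + 1L, j + 1L] <- f_ext; dirF[i + 1L, j + 1L] <- 2L }
      else { F_[i + 1L, j + 1L] <- f_open; dirF[i + 1L, j + 1L] <- 1L }
      dg <- H[i, j] + Si[s[j] + 1L]
      h <- 0; d <- 0L
      if (dg > h) { h <- dg; d <- 1L }
      if (E[i + 1L, j + 1L] > h) { h <- E[i + 1L, j + 1L]; d <- 2L }
      if (F_[i + 1L, j + 1L] > h) { h <- F_[i + 1L, j + 1L]; d <- 3L }
      H[i + 1L, j + 1L] <- h; dirH[i + 1L, j + 1L] <- d
      if (h > best) { best <- h; bi <- i; bj <- j }
    }
  }
  if (best == 0)
    return(list(score = 0, q_start = 0L, q_end = 0L, s_start = 0L,
                s_end = 0L, ops = ""))
  ops <- character()
  i <- bi + 1L; j <- bj + 1L
  state <- 0L
  repeat {
    if (state == 0L) {
      d <- dirH[i, j]
      if (d == 0L) break
      if (d == 1L) { ops <- c(ops, "M"); i <- i - 1L; j <- j - 1L }
      else state <- d
    } else if (state == 2L) {
      ops <- c(ops, "D")
      ext <- dirE[i, j] == 2L
      j <- j - 1L
      if (!ext) state <- 0L
    } else {
      ops <- c(ops, "I")
      ext <- dirF[i, j] == 2L
      i <- i - 1L
      if (!ext) state <- 0L
    }
  }
  list(score = best, q_start = i - 1L, q_end = bi, s_start = j - 1L,
       s_end = bj, ops = paste(rev(ops), collapse = ""))
}

#' Classical query-indexed two-hit scan (reference implementation)
#'
#' The last-hit-array method of query-indexed protein search: every subject
#' is scanned position by position; subject words matching a query word
#' exactly or as a neighbor produce hits; a per-diagonal last-hit array
#' emits a two-hit pair when the distance on the diagonal falls in
#' `[overlap, window)`. Used as the equivalence oracle for
#' [bin_and_filter()] and [search_block()].
#'
#' @param query Residue string or integer codes.
#' @param db_seqs A `protein_db`/`db_block`, or list of integer code vectors.
#' @param params A `search_params`.
#' @return List: `pairs` tibble (`seq_id`, `subject_offset`, `diagonal` of
#'   each triggering hit) and `hsps` tibble from ungapped extension of those
#'   pairs (0-based half-open, score >= `params$ungapped_cutoff`).
#' @export
naive_two_hit_scan <- function(query, db_seqs, params = search_params()) {
  q <- .query_codes(query)
  seqs <- if (inherits(db_seqs, "protein_db") ||
              inherits(db_seqs, "db_block")) db_seqs$seqs else db_seqs
  fin <- .finalize_params(params)
  W <- fin$W
  qlen <- length(q)
  n_words <- .alpha_size^W
  # query lookup: for every word, the query positions it matches (exactly or
  # as a neighbor of the query's word)
  match_pos <- vector("list", n_words)
  if (qlen >= W) {
    for (p in 0:(qlen - W)) {
      wcodes <- q[(p + 1L):(p + W)]
      if (any(wcodes >= .alpha_size)) next
      w <- word_id(wcodes)
      for (v in c(w, compute_neighbor_words(w, fin$m, fin$T, W)))
        match_pos[[v + 1L]] <- c(match_pos[[v + 1L]], p)
    }
  }
  pr_seq <- integer(); pr_off <- integer(); pr_diag <- integer()
  hs <- list()
  for (si in seq_along(seqs)) {
    s <- seqs[[si]]
    slen <- length(s)
    if (slen < W) next
    # last-hit array over diagonals, indexed diagonal + qlen
    last_off <- rep(NA_integer_, qlen + slen)
    hits_off <- integer(); hits_diag <- integer()
    for (o in 0:(slen - W)) {
      wcodes <- s[(o + 1L):(o + W)]
      if (any(wcodes >= .alpha_size)) next
      w <- word_id(wcodes)
      for (p in match_pos[[w + 1L]]) {
        diag <- o - p
        di <- diag + qlen
        lo <- last_off[di]
        if (!is.na(lo)) {
          d <- o - lo
          if (d >= fin$overlap && d < fin$window) {
            hits_off <- c(hits_off, o); hits_diag <- c(hits_diag, diag)
          }
        }
        last_off[di] <- o
      }
    }
    if (length(hits_off)) {
      pr_seq <- c(pr_seq, rep.int(si - 1L, length(hits_off)))
      pr_off <- c(pr_off, hits_off)
      pr_diag <- c(pr_diag, hits_diag)
      # ungapped extension with the diagonal-local gating, offsets ascending
      ord <- order(hits_diag, hits_off)
      cur_diag <- NA_integer_; last_end <- -1L
      for (k in ord) {
        diag <- hits_diag[k]; off <- hits_off[k]
        if (is.na(cur_diag) || diag != cur_diag) {
          cur_diag <- diag; last_end <- -1e9
        }
        if (off <= last_end) next
        v <- .ungapped_one_cpp(q, s, off - diag, off, W, fin$m,
                               fin$xdrop_ungapped)
        last_end <- v[4] - 1L
        if (v[5] >= fin$ungapped_cutoff)
          hs[[length(hs) + 1L]] <- c(si - 1L, v)
      }
    }
  }
  hsps <- if (length(hs)) {
    mh <- do.call(rbind, hs)
    colnames(mh) <- c("seq_id", "q_start", "q_end", "s_start", "s_end",
                      "score")
    unique(tibble::as_tibble(mh))
  } else tibble::tibble(seq_id = integer(), q_start = integer(),
                        q_end = integer(), s_start = integer(),
                        s_end = integer(), score = integer())
  list(pairs = tibble::tibble(seq_id = pr_seq, subject_offset = pr_off,
                              diagonal = pr_diag),
       hsps = hsps)
}

#' Query-indexed search pipeline (reference implementation)
#'
#' Seeds with [naive_two_hit_scan()] and runs the same gapped stage and
#' statistics as [search_block()], so the two pipelines differ only in how
#' hits are found: database index versus query index.
#'
#' @param query Residue string or integer codes.
#' @param db A `protein_db` (use the sorted database to get the same
#'   sequence ids as a single-block index).
#' @param params A `search_params`.
#' @param db_stats Optional list(letters, n_seqs) search space override.
#' @return Alignment tibble with the same columns as [search_block()].
#' @export
naive_search <- function(query, db, params = search_params(),
                         db_stats = NULL) {
  stopifnot(inherits(db, "protein_db"))
  q <- .query_codes(query)
  fin <- .finalize_params(params)
  sc <- naive_two_hit_scan(q, db, params)
  hsps <- sc$hsps
  names(hsps)[names(hsps) == "seq_id"] <- "id"
  letters <- if (is.null(db_stats)) sum(db$meta$length) else db_stats$letters
  n_seqs <- if (is.null(db_stats)) nrow(db$meta) else db_stats$n_seqs
  .gapped_stage(q, hsps,
                get_seq = function(id) db$seqs[[id + 1L]],
                get_acc = function(id) db$meta$accession[[id + 1L]],
                fin, letters, n_seqs)
}
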