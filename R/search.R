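#' Search parameters
#'
#' Tunables for seeding, extension, scoring, and reporting. Defaults follow
#' the usual protein-BLAST settings: word length 3, neighbor threshold 11,
#' two-hit window 40 and minimum hit distance equal to the word length,
#' ungapped X-drop of 7 bits, a raw gapped trigger score of 22, gapped
#' X-drop of 15 bits, BLOSUM62 with affine gaps 11/1 (a length-L gap costs
#' `gap_open + gap_extend * L`), E-value cutoff 10, at most 500 reported
#' alignments per query.
#'
#' @param W Word length.
#' @param T Neighbor threshold (word-score units).
#' @param window Two-hit window: max distance between hits on a diagonal.
#' @param overlap Minimum distance between the two hits (non-overlap rule).
#' @param xdrop_ungapped_bits Ungapped X-drop, in bits.
#' @param xdrop_gapped_bits Gapped X-drop, in bits (`Inf` disables pruning).
#' @param gap_trigger Raw ungapped score needed to trigger gapped extension.
#' @param ungapped_cutoff Raw score an ungapped HSP must reach to be kept
#'   (default: the gapped trigger).
#' @param gap_open,gap_extend Affine gap penalties.
#' @param matrix Scoring matrix name or 21x21 matrix.
#' @param evalue_cutoff Maximum reported E-value.
#' @param max_reported Maximum alignments reported per query.
#' @return A `search_params` list.
#' @export
search_params <- function(W = 3L, T = 11, window = 40L, overlap = W,
                          xdrop_ungapped_bits = 7, xdrop_gapped_bits = 15,
                          gap_trigger = 22L, ungapped_cutoff = gap_trigger,
                          gap_open = 11L, gap_extend = 1L,
                          matrix = "BLOSUM62", evalue_cutoff = 10,
                          max_reported = 500L) {
  stopifnot(W >= 1, overlap <= window, gap_open > 0, gap_extend > 0,
            xdrop_ungapped_bits > 0, xdrop_gapped_bits > 0,
            evalue_cutoff > 0, max_reported >= 1)
  structure(list(W = as.integer(W), T = T, window = as.integer(window),
                 overlap = as.integer(overlap),
                 xdrop_ungapped_bits = xdrop_ungapped_bits,
                 xdrop_gapped_bits = xdrop_gapped_bits,
                 gap_trigger = gap_trigger,
                 ungapped_cutoff = ungapped_cutoff,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), matrix = matrix,
                 evalue_cutoff = evalue_cutoff,
                 max_reported = as.integer(max_reported)),
            class = "search_params")
}

# resolve matrix object, Karlin-Altschul constants and raw X-drops once
.finalize_params <- function(params) {
  m <- substitution_matrix(params$matrix)
  kp_u <- karlin_params(attr(m, "matrix_name") %||% "BLOSUM62", gapped = FALSE)
  kp_g <- karlin_params(attr(m, "matrix_name") %||% "BLOSUM62",
                        params$gap_open, params$gap_extend, gapped = TRUE)
  xu <- if (is.finite(params$xdrop_ungapped_bits))
    as.integer(floor(params$xdrop_ungapped_bits * log(2) / kp_u$lambda))
  else .Machine$integer.max %/% 4L
  xg <- if (is.finite(params$xdrop_gapped_bits))
    floor(params$xdrop_gapped_bits * log(2) / kp_g$lambda)
  else Inf
  c(params, list(m = m, kp_u = kp_u, kp_g = kp_g,
                 xdrop_ungapped = xu, xdrop_gapped = xg))
}

.query_codes <- function(query) {
  if (is.character(query)) {
    codes <- encode_residues(query)
    attributes(codes) <- NULL
    codes
  } else if (is.numeric(query)) {
    as.integer(query)
  } else stop("query must be a residue string or integer codes")
}

#' Detect word hits against a block index
#'
#' For each query position carrying an indexable word, the posting runs of
#' that word and of each of its neighbors are decoded from the compressed
#' index, and every decoded position becomes a hit in the first-level bin of
#' its diagonal (subject offset minus query offset). Hits from one
#' posting-run traversal are appended in decoded (subject-offset sorted)
#' order, so bins are filled sequentially.
#'
#' @param query Residue string or integer codes; length must be at least W.
#' @param index A `block_index`.
#' @param params A `search_params` (only W and T metadata are checked).
#' @return Tibble of hits in bin-scan order (ascending diagonal): columns
#'   `diagonal`, `seq_id`, `subject_offset`; attributes `query_len`,
#'   `n_seqs`.
#' @export
detect_hits <- function(query, index, params = search_params()) {
  codes <- .query_codes(query)
  stopifnot(inherits(index, "block_index"), length(codes) >= params$W)
  if (params$W != index$W)
    stop("params W (", params$W, ") does not match index W (", index$W, ")")
  res <- .detect_hits_cpp(codes, index$entry_start, index$delta, index$count,
                          index$sid_start, index$sids, index$nb_start,
                          index$nb, index$W, index$asize, index$max_len)
  qlen <- res$qlen
  bins <- tibble::tibble(
    diagonal = rep.int(seq_len(length(res$bin_start) - 1L) - qlen,
                       diff(res$bin_start)),
    seq_id = res$seq_id,
    subject_offset = res$subject_offset
  )
  attr(bins, "query_len") <- qlen
  attr(bins, "n_seqs") <- index$n_seqs
  bins
}

#' Two-hit filter into second-level bins
#'
#' Scans first-level bins in ascending diagonal order with a last-hit array
#' keyed by sequence id. A hit whose distance to the previous hit on the
#' same diagonal of the same sequence lies in `[overlap, window)` is emitted
#' (the triggering, second hit with its diagonal) into the second-level bin
#' of its sequence; the last-hit record is always updated. Within a
#' second-level bin, emitted hits are naturally ordered by diagonal.
#'
#' @param bins Hit tibble from [detect_hits()] (bin-scan order).
#' @param params A `search_params`.
#' @return Tibble grouped by sequence bin: `seq_id`, `subject_offset`,
#'   `diagonal`; attributes `query_len`, `n_seqs`, `bin2_start`.
#' @export
bin_and_filter <- function(bins, params = search_params()) {
  n_seqs <- attr(bins, "n_seqs")
  stopifnot(!is.null(n_seqs))
  res <- .filter_pairs_cpp(as.integer(bins$diagonal),
                           as.integer(bins$seq_id),
                           as.integer(bins$subject_offset),
                           n_seqs, params$window, params$overlap)
  out <- tibble::tibble(seq_id = res$seq_id,
                        subject_offset = res$subject_offset,
                        diagonal = res$diagonal)
  attr(out, "query_len") <- attr(bins, "query_len")
  attr(out, "n_seqs") <- n_seqs
  attr(out, "bin2_start") <- res$bin2_start
  out
}

#' Ungapped X-drop extension from a two-hit trigger
#'
#' Extends along the diagonal from the triggering word, left then right,
#' stopping when the running score drops more than the ungapped X-drop below
#' its running maximum; extensions never cross sequence boundaries.
#'
#' @param query,subject Residue strings or integer codes.
#' @param pair List or one-row data frame with `subject_offset` and
#'   `diagonal` of the triggering hit.
#' @param params A `search_params`.
#' @return One-row tibble (`q_start`, `q_end`, `s_start`, `s_end`, `score`;
#'   0-based half-open coordinates) if the score reaches
#'   `params$ungapped_cutoff`, else `NULL`.
#' @export
ungapped_extend <- function(query, subject, pair, params = search_params()) {
  q <- .query_codes(query); s <- .query_codes(subject)
  fin <- .finalize_params(params)
  s_pos <- as.integer(pair$subject_offset)
  q_pos <- s_pos - as.integer(pair$diagonal)
  v <- .ungapped_one_cpp(q, s, q_pos, s_pos, fin$W, fin$m, fin$xdrop_ungapped)
  if (v[5] < fin$ungapped_cutoff) return(NULL)
  tibble::tibble(q_start = v[1], q_end = v[2], s_start = v[3], s_end = v[4],
                 score = v[5])
}

# seed for gapped extension: midpoint of the best-scoring length-11 window
# of the HSP diagonal (the whole HSP if shorter)
.seed_point <- function(qcodes, scodes, q_start, s_start, len, m) {
  sc <- m[cbind(qcodes[(q_start + 1L):(q_start + len)] + 1L,
                scodes[(s_start + 1L):(s_start + len)] + 1L)]
  wnd <- min(11L, len)
  cs <- cumsum(c(0L, sc))
  sums <- cs[(wnd + 1L):(len + 1L)] - cs[1L:(len - wnd + 1L)]
  k <- which.max(sums) - 1L  # first maximal window, 0-based
  mid <- k + (wnd - 1L) %/% 2L
  c(q_start + mid, s_start + mid)
}

#' Gapped X-drop extension from an HSP
#'
#' Seeds at the midpoint of the HSP's best-scoring window and extends in
#' both directions with an affine-gap X-drop dynamic program, producing a
#' traceback. With an unbounded X-drop the score equals the optimal local
#' alignment score constrained to pass through the seed.
#'
#' @param query,subject Residue strings or integer codes.
#' @param hsp One-row data frame from [ungapped_extend()] (0-based half-open
#'   `q_start`, `q_end`, `s_start`, `s_end`, `score`).
#' @param params A `search_params`.
#' @return One-row tibble with `score`, 0-based half-open ranges, the edit
#'   string `ops` (M = aligned pair, I = query-only, D = subject-only),
#'   `identities`, `positives`, `gaps`, `length`; `NULL` if the HSP score is
#'   below `params$gap_trigger`.
#' @export
gapped_extend <- function(query, subject, hsp, params = search_params()) {
  if (hsp$score < params$gap_trigger) return(NULL)
  q <- .query_codes(query); s <- .query_codes(subject)
  fin <- .finalize_params(params)
  seed <- .seed_point(q, s, hsp$q_start, hsp$s_start,
                      hsp$q_end - hsp$q_start, fin$m)
  g <- .gapped_extend_cpp(q, s, seed[1], seed[2], fin$m, fin$gap_open,
                          fin$gap_extend,
                          if (is.finite(fin$xdrop_gapped)) fin$xdrop_gapped
                          else 1e18)
  tibble::tibble(score = g$score, q_start = g$q_start, q_end = g$q_end,
                 s_start = g$s_start, s_end = g$s_end, ops = g$ops,
                 identities = g$identities, positives = g$positives,
                 gaps = g$gaps, length = g$length)
}

# ungapped stage over second-level bins; returns HSP tibble with local ids.
# pairs must be grouped per sequence, ordered by (diagonal, subject offset);
# per diagonal, a seed not passing the right end of the previous extension
# on that diagonal is skipped (order-independent gating).
.ungapped_stage <- function(qcodes, seqs, pairs, fin) {
  mat <- .ungapped_block_cpp(qcodes, seqs, attr(pairs, "bin2_start"),
                             as.integer(pairs$subject_offset),
                             as.integer(pairs$diagonal),
                             fin$W, fin$m, fin$xdrop_ungapped,
                             as.integer(fin$ungapped_cutoff))
  hsps <- tibble::as_tibble(mat)
  unique(hsps)
}

# gapped stage: HSPs above the trigger, strongest first, containment-deduped
# against already-kept alignments of the same subject, then E-value filter.
# `ids` are keys into get_seq/get_acc; db_letters/db_seqs define the search
# space for the E-value.
.gapped_stage <- function(qcodes, hsps, get_seq, get_acc, fin,
                          db_letters, db_seqs) {
  empty <- tibble::tibble(
    seq_id = integer(),
    subject = character(), raw_score = integer(), bit_score = numeric(),
    evalue = numeric(), q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(), length = integer(),
    identities = integer(), positives = integer(), gaps = integer(),
    ops = character())
  if (nrow(hsps) == 0L) return(empty)
  keep <- hsps$score >= fin$gap_trigger
  if (!any(keep)) return(empty)
  h_id <- hsps$id[keep]
  h_qs <- hsps$q_start[keep]; h_qe <- hsps$q_end[keep]
  h_ss <- hsps$s_start[keep]; h_se <- hsps$s_end[keep]
  h_sc <- hsps$score[keep]
  ord <- order(-h_sc, h_id, h_qs, h_ss, h_qe, h_se)
  spans <- new.env(parent = emptyenv())  # per id: kept span matrix
  n_kept <- 0L
  o_id <- integer(); o_g <- vector("list", 0L)
  for (i in ord) {
    key <- as.character(h_id[i])
    sp <- spans[[key]]
    if (!is.null(sp)) {
      inside <- sp[, 1] <= h_qs[i] & h_qe[i] <= sp[, 2] &
        sp[, 3] <= h_ss[i] & h_se[i] <= sp[, 4]
      if (any(inside)) next
    }
    scodes <- get_seq(h_id[i])
    seed <- .seed_point(qcodes, scodes, h_qs[i], h_ss[i], h_qe[i] - h_qs[i],
                        fin$m)
    g <- .gapped_extend_cpp(qcodes, scodes, seed[1], seed[2], fin$m,
                            fin$gap_open, fin$gap_extend,
                            if (is.finite(fin$xdrop_gapped))
                              fin$xdrop_gapped else 1e18)
    spans[[key]] <- rbind(sp, c(g$q_start, g$q_end, g$s_start, g$s_end))
    n_kept <- n_kept + 1L
    o_id[n_kept] <- h_id[i]
    o_g[[n_kept]] <- g
  }
  if (n_kept == 0L) return(empty)
  raw <- vapply(o_g, `[[`, 0L, "score")
  out <- tibble::tibble(
    seq_id = o_id,
    subject = vapply(o_id, get_acc, ""),
    raw_score = raw,
    bit_score = bit_score(raw, fin$kp_g),
    evalue = evalue(raw, length(qcodes), db_letters, db_seqs, fin$kp_g),
    q_start = vapply(o_g, `[[`, 0L, "q_start"),
    q_end = vapply(o_g, `[[`, 0L, "q_end"),
    s_start = vapply(o_g, `[[`, 0L, "s_start"),
    s_end = vapply(o_g, `[[`, 0L, "s_end"),
    length = vapply(o_g, `[[`, 0L, "length"),
    identities = vapply(o_g, `[[`, 0L, "identities"),
    positives = vapply(o_g, `[[`, 0L, "positives"),
    gaps = vapply(o_g, `[[`, 0L, "gaps"),
    ops = vapply(o_g, `[[`, "", "ops"))
  out <- out[out$evalue <= fin$evalue_cutoff, , drop = FALSE]
  # different seeds can extend to the same aligned region (possibly with
  # equal-scoring alternative gap placements): keep one alignment per
  # (subject, span), the best-scoring, tie-broken on the edit string
  ord2 <- order(out$seq_id, out$q_start, out$q_end, out$s_start, out$s_end,
                -out$raw_score, out$ops)
  out <- out[ord2, , drop = FALSE]
  span <- paste(out$seq_id, out$q_start, out$q_end, out$s_start, out$s_end)
  out <- out[!duplicated(span), , drop = FALSE]
  out[order(out$evalue, -out$raw_score, out$subject, out$q_start,
            out$s_start), , drop = FALSE]
}

#' Search one indexed block
#'
#' Full block-local chain: hit detection over the compressed index,
#' two-level binning with the two-hit filter, ungapped X-drop extension,
#' then gapped extension with traceback on HSPs above the trigger, with
#' containment deduplication, E-values, and deterministic ranking.
#'
#' @param query Residue string or integer codes.
#' @param xblock An `indexed_block` (see [index_database()]), or a list with
#'   elements `block` (`db_block`) and `index` (`block_index`).
#' @param params A `search_params`.
#' @param db_stats Optional list(letters, n_seqs) giving the whole-database
#'   search space for E-values; defaults to the block's own.
#' @return Tibble of alignments (one per subject segment pair): accession,
#'   scores, E-value, 0-based half-open ranges, edit string.
#' @export
search_block <- function(query, xblock, params = search_params(),
                         db_stats = NULL) {
  block <- xblock$block; index <- xblock$index
  stopifnot(inherits(block, "db_block"), inherits(index, "block_index"))
  codes <- .query_codes(query)
  fin <- .finalize_params(params)
  if (length(codes) < fin$W) stop("query shorter than the word length")
  bins <- detect_hits(codes, index, params)
  pairs <- bin_and_filter(bins, params)
  hsps <- .ungapped_stage(codes, block$seqs, pairs, fin)
  names(hsps)[names(hsps) == "seq_id"] <- "id"
  letters <- if (is.null(db_stats)) block$letters else db_stats$letters
  n_seqs <- if (is.null(db_stats)) length(block$seqs) else db_stats$n_seqs
  .gapped_stage(codes, hsps,
                get_seq = function(id) block$seqs[[id + 1L]],
                get_acc = function(id) block$accession[[id + 1L]],
                fin, letters, n_seqs)
}
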