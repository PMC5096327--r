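.gap_opens <- function(ops) {
  vapply(strsplit(ops, ""), function(o) {
    r <- rle(o)
    sum(r$values %in% c("I", "D"))
  }, 0L)
}

.fmt_evalue <- function(e) {
  ifelse(e < 1e-180, "0.0",
         ifelse(e < 0.001, sprintf("%.0e", e), sprintf("%.3g", e)))
}

#' Tabular report (12-column BLAST-style)
#'
#' Columns: query, subject, percent identity, alignment length, mismatches,
#' gap openings, query start/end, subject start/end (1-based inclusive),
#' E-value, bit score. Tab-separated, one line per alignment.
#'
#' @param result A `batch_result` from [run_batch()].
#' @return Character vector of report lines.
#' @export
format_tabular <- function(result) {
  h <- result$hits
  if (nrow(h) == 0L) return(character())
  sprintf("%s\t%s\t%.3f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
          h$query, h$subject, 100 * h$identities / h$length, h$length,
          h$length - h$identities - h$gaps, .gap_opens(h$ops),
          h$q_start + 1L, h$q_end, h$s_start + 1L, h$s_end,
          .fmt_evalue(h$evalue), h$bit_score)
}

.aligned_strings <- function(qstr, sstr, hit) {
  qa <- character(); sa <- character(); mid <- character()
  iq <- hit$q_start; js <- hit$s_start
  m <- substitution_matrix("BLOSUM62")
  for (c in strsplit(hit$ops, "")[[1]]) {
    if (c == "M") {
      a <- substr(qstr, iq + 1L, iq + 1L); b <- substr(sstr, js + 1L, js + 1L)
      qa <- c(qa, a); sa <- c(sa, b)
      mid <- c(mid, if (a == b) a else if (m[a, b] > 0) "+" else " ")
      iq <- iq + 1L; js <- js + 1L
    } else if (c == "I") {
      qa <- c(qa, substr(qstr, iq + 1L, iq + 1L)); sa <- c(sa, "-")
      mid <- c(mid, " "); iq <- iq + 1L
    } else {
      qa <- c(qa, "-"); sa <- c(sa, substr(sstr, js + 1L, js + 1L))
      mid <- c(mid, " "); js <- js + 1L
    }
  }
  list(q = qa, s = sa, mid = mid)
}

#' Pairwise report
#'
#' Human-readable report in the familiar pairwise layout: per query, per
#' subject, score/E-value/identity summary and 60-column alignment blocks.
#' Needs the query and subject residues, which the result tibble does not
#' carry.
#'
#' @param result A `batch_result`.
#' @param queries The queries given to [run_batch()] (named character vector
#'   or `protein_db`).
#' @param db The searched `protein_db` (any sort order; looked up by
#'   accession).
#' @return Character vector of report lines.
#' @export
format_pairwise <- function(result, queries, db) {
  qs <- .normalize_queries(queries)
  qstrs <- stats::setNames(
    vapply(qs$codes, decode_residues, ""), qs$accession)
  sstrs <- stats::setNames(
    vapply(db$seqs, decode_residues, ""), db$meta$accession)
  out <- character()
  h <- result$hits
  for (q in unique(h$query)) {
    out <- c(out, sprintf("Query= %s", q),
             sprintf("         (%d letters)", nchar(qstrs[[q]])), "")
    hq <- h[h$query == q, , drop = FALSE]
    for (i in seq_len(nrow(hq))) {
      hit <- hq[i, ]
      out <- c(out, sprintf("> %s", hit$subject),
               sprintf(" Score = %.1f bits (%d), Expect = %s",
                       hit$bit_score, hit$raw_score, .fmt_evalue(hit$evalue)),
               sprintf(" Identities = %d/%d (%d%%), Positives = %d/%d (%d%%), Gaps = %d/%d (%d%%)",
                       hit$identities, hit$length,
                       round(100 * hit$identities / hit$length),
                       hit$positives, hit$length,
                       round(100 * hit$positives / hit$length),
                       hit$gaps, hit$length,
                       round(100 * hit$gaps / hit$length)), "")
      al <- .aligned_strings(qstrs[[q]], sstrs[[hit$subject]], hit)
      qpos <- hit$q_start + 1L; spos <- hit$s_start + 1L
      for (k in seq(1L, length(al$q), by = 60L)) {
        kk <- k:min(k + 59L, length(al$q))
        nq <- sum(al$q[kk] != "-"); ns <- sum(al$s[kk] != "-")
        out <- c(out,
                 sprintf("Query  %-5d %s  %d", qpos,
                         paste(al$q[kk], collapse = ""), qpos + nq - 1L),
                 sprintf("             %s", paste(al$mid[kk], collapse = "")),
                 sprintf("Sbjct  %-5d %s  %d", spos,
                         paste(al$s[kk], collapse = ""), spos + ns - 1L), "")
        qpos <- qpos + nq; spos <- spos + ns
      }
    }
  }
  out
}

#' Write a FASTA file
#'
#' @param sequences Named character vector of residue strings, or a
#'   `protein_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (inherits(sequences, "protein_db")) {
    nm <- ifelse(nzchar(sequences$meta$description),
                 paste(sequences$meta$accession, sequences$meta$description),
                 sequences$meta$accession)
    sequences <- stats::setNames(
      vapply(sequences$seqs, decode_residues, ""), nm)
  }
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
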