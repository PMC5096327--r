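#' Karlin-Altschul parameters
#'
#' Looks up the published (lambda, K, H) constants for a scoring system.
#' Gapped constants are keyed by (matrix, gap_open, gap_extend); only
#' combinations present in the published table are accepted, and anything
#' else raises an error rather than guessing.
#'
#' @param matrix Matrix name (currently "BLOSUM62").
#' @param gap_open,gap_extend Affine gap penalties (a length-L gap costs
#'   `gap_open + gap_extend * L`).
#' @param gapped If `FALSE`, return the ungapped constants for the matrix.
#' @return List with `lambda`, `K`, `H`, `gapped`, `matrix`.
#' @export
karlin_params <- function(matrix = "BLOSUM62", gap_open = 11L,
                          gap_extend = 1L, gapped = TRUE) {
  tab <- list(
    BLOSUM62 = list(
      ungapped = c(lambda = 0.3176, K = 0.134, H = 0.4012),
      gapped = list("11,1" = c(lambda = 0.267, K = 0.041, H = 0.140))
    )
  )
  if (!matrix %in% names(tab))
    stop("no Karlin-Altschul constants for matrix ", matrix)
  if (!gapped) {
    v <- tab[[matrix]]$ungapped
  } else {
    key <- paste0(gap_open, ",", gap_extend)
    g <- tab[[matrix]]$gapped
    if (!key %in% names(g))
      stop("no Karlin-Altschul constants for ", matrix, " with gap penalties (",
           gap_open, ", ", gap_extend, "); supported: ",
           paste(names(g), collapse = " "))
    v <- g[[key]]
  }
  list(lambda = unname(v["lambda"]), K = unname(v["K"]), H = unname(v["H"]),
       gapped = gapped, matrix = matrix)
}

#' Bit score of a raw alignment score
#'
#' `bits = (lambda * raw - ln K) / ln 2`.
#'
#' @param raw Raw (matrix-sum) score, vectorised.
#' @param kp Constants from [karlin_params()].
#' @return Numeric bit scores.
#' @export
bit_score <- function(raw, kp) {
  (kp$lambda * raw - log(kp$K)) / log(2)
}

# effective-length adjustment: l solves l = ln(K (m-l)(n-N l)) / H, iterated
# to a fixed point and floored so effective lengths stay positive
.length_adjustment <- function(kp, m, n, N) {
  l <- 0
  for (i in 1:20) {
    me <- max(m - l, 1)
    ne <- max(n - N * l, 1)
    l_new <- log(kp$K * me * ne) / kp$H
    if (!is.finite(l_new) || l_new < 0) l_new <- 0
    if (abs(l_new - l) < 1e-6) { l <- l_new; break }
    l <- l_new
  }
  floor(l)
}

#' Expectation value of a raw score
#'
#' `E = K * m' * n' * exp(-lambda * raw)` with the standard effective-length
#' adjustment: `m' = m - l`, `n' = db_letters - db_seqs * l`, where `l` is the
#' fixed point of `l = ln(K m' n') / H`. Set `adjust = FALSE` for the textbook
#' unadjusted formula.
#'
#' @param raw Raw score(s).
#' @param query_len Query length (residues).
#' @param db_letters Total residues in the database.
#' @param db_seqs Number of database sequences.
#' @param kp Constants from [karlin_params()].
#' @param adjust Apply the length adjustment (default `TRUE`).
#' @return Numeric E-values.
#' @export
evalue <- function(raw, query_len, db_letters, db_seqs, kp, adjust = TRUE) {
  stopifnot(query_len >= 1, db_letters >= 1, db_seqs >= 1)
  l <- if (adjust) .length_adjustment(kp, query_len, db_letters, db_seqs) else 0
  m_eff <- max(query_len - l, 1)
  n_eff <- max(db_letters - db_seqs * l, 1)
  kp$K * m_eff * n_eff * exp(-kp$lambda * raw)
}
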