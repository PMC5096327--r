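# Robinson-Robinson (1991) background amino-acid frequencies, the standard
# protein-search null composition, in package alphabet order.
.rr_freqs <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)

#' Specification for a synthetic protein database
#'
#' Sequences are i.i.d. draws from the Robinson-Robinson background
#' composition with log-normal lengths truncated to `[min_len, max_len]`
#' (most real protein databases concentrate between 60 and 1000 residues).
#' `n_planted` homolog pairs share a segment copied from a donor into a
#' receiver after point substitutions to the target identity and a small
#' number of short indels.
#'
#' @param n_sequences Database size.
#' @param length_meanlog,length_sdlog Log-normal length parameters.
#' @param min_len,max_len Length truncation bounds.
#' @param n_planted Number of planted homolog pairs.
#' @param identity Target fractional identity of planted segments (0.25-1).
#' @param indel_rate Per-position probability of a short indel in the
#'   planted segment (0-0.2).
#' @param seg_len Planted segment length (capped by sequence lengths).
#' @param seed RNG seed; the generator is fully reproducible given the seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_sequences = 200L, length_meanlog = log(230),
                           length_sdlog = 0.45, min_len = 60L,
                           max_len = 1000L, n_planted = 10L, identity = 0.6,
                           indel_rate = 0.02, seg_len = 120L, seed = 1L) {
  if (identity < 0.25 || identity > 1)
    stop("infeasible target identity: ", identity)
  if (indel_rate < 0 || indel_rate > 0.2)
    stop("infeasible indel rate: ", indel_rate)
  if (2L * n_planted > n_sequences)
    stop("n_planted too large for the database size")
  structure(list(n_sequences = as.integer(n_sequences),
                 length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog, min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 n_planted = as.integer(n_planted), identity = identity,
                 indel_rate = indel_rate, seg_len = as.integer(seg_len),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

.random_codes <- function(n) {
  sample.int(20L, n, replace = TRUE, prob = .rr_freqs) - 1L
}

# Mutate a planted segment: k substitutions plus n_ind single-residue
# indels. Indel sites keep a clear margin from every substitution and from
# each other so the mutation is recoverable by alignment: a gap sliding
# within identical flanking context never changes the match count, so the
# post-hoc measured identity stays at the planted value. Insertions are
# dropped (not converted) when the segment may not grow past max_grow.
.mutate_segment <- function(seg, k, n_ind, max_grow) {
  L <- length(seg)
  margin <- 4L
  # indel sites first, mutually spaced and away from the ends
  indel_pos <- integer()
  cand <- seq(margin + 1L, L - margin)
  for (i in seq_len(n_ind)) {
    ok <- cand[!cand %in% as.vector(outer(indel_pos, -margin:margin, `+`))]
    if (!length(ok)) break
    indel_pos <- c(indel_pos, sample(ok, 1L))
  }
  # substitution sites anywhere outside the indel margins; the substitution
  # quota has priority, so indels are shed when a short segment cannot
  # host both
  repeat {
    sub_cand <- setdiff(seq_len(L),
                        as.vector(outer(indel_pos, -margin:margin, `+`)))
    if (k <= length(sub_cand) || length(indel_pos) == 0L) break
    indel_pos <- indel_pos[-length(indel_pos)]
  }
  if (k > length(sub_cand))
    stop("infeasible identity/indel combination: too few mutable positions")
  sub_pos <- if (k > 0L) sample(sub_cand, k) else integer()
  for (p in sub_pos) {
    alt <- setdiff(0:19, seg[p])
    seg[p] <- sample(alt, 1L, prob = .rr_freqs[alt + 1L])
  }
  # apply indels right to left so earlier positions stay valid
  grow <- 0L
  for (p in sort(indel_pos, decreasing = TRUE)) {
    if (runif(1) < 0.5 && grow < max_grow) {
      seg <- append(seg, .random_codes(1L), after = p)
      grow <- grow + 1L
    } else {
      seg <- seg[-p]
    }
  }
  list(seg = seg, n_sub = length(sub_pos), n_indel = length(indel_pos))
}

#' Generate a synthetic database with planted homologies
#'
#' Deterministic given `spec$seed`. The returned truth table records, for
#' each planted pair, the donor and receiver accessions and the 0-based
#' half-open coordinates of the shared segment in both sequences, plus the
#' exact substitution and indel counts applied.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `db` (a `protein_db`) and `truth` (a tibble).
#' @export
generate_database <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  n <- spec$n_sequences
  lens <- pmin(pmax(round(rlnorm(n, spec$length_meanlog, spec$length_sdlog)),
                    spec$min_len), spec$max_len)
  seqs <- lapply(lens, .random_codes)
  acc <- sprintf("SYN%05d", seq_len(n))
  idx <- sample.int(n, 2L * spec$n_planted)
  donors <- idx[seq_len(spec$n_planted)]
  receivers <- idx[spec$n_planted + seq_len(spec$n_planted)]
  truth <- vector("list", spec$n_planted)
  for (i in seq_len(spec$n_planted)) {
    d <- donors[i]; r <- receivers[i]
    L <- min(spec$seg_len, lens[d] - 2L, lens[r] - 10L)
    d_start <- sample.int(lens[d] - L + 1L, 1L) - 1L
    seg <- seqs[[d]][(d_start + 1L):(d_start + L)]
    k <- round((1 - spec$identity) * L)
    n_ind <- rbinom(1L, L, spec$indel_rate)
    mu <- .mutate_segment(seg, k, n_ind, max_grow = lens[r] - 2L - L)
    Lm <- length(mu$seg)
    r_start <- sample.int(lens[r] - Lm + 1L, 1L) - 1L
    sq <- seqs[[r]]
    sq <- c(sq[seq_len(r_start)], mu$seg,
            sq[seq.int(r_start + Lm + 1L, length.out = lens[r] - r_start - Lm)])
    seqs[[r]] <- sq
    truth[[i]] <- tibble::tibble(
      pair = i, donor = acc[d], receiver = acc[r],
      donor_start = d_start, donor_end = d_start + L,
      receiver_start = r_start, receiver_end = r_start + Lm,
      target_identity = spec$identity, n_sub = mu$n_sub,
      n_indel = mu$n_indel)
  }
  db <- new_protein_db(acc, rep("", n), seqs)
  list(db = db, truth = do.call(rbind, truth))
}

#' Measured identity of planted segments
#'
#' Re-aligns each planted donor segment to its receiver segment globally
#' (end to end, so mutation-dense ends are not trimmed away) and reports
#' identity as matches over aligned residue pairs, gap columns excluded —
#' the quantity the generator's substitution count controls.
#'
#' @param gen Output of [generate_database()].
#' @param gap_open,gap_extend Affine gap penalties for the measuring
#'   alignment (defaults 11/1, BLOSUM62).
#' @return Tibble: one row per planted pair with `measured_identity`.
#' @export
planted_identity <- function(gen, gap_open = 11L, gap_extend = 1L) {
  db <- gen$db; truth <- gen$truth
  byacc <- stats::setNames(db$seqs, db$meta$accession)
  out <- truth
  out$measured_identity <- NA_real_
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    dseg <- decode_residues(byacc[[tr$donor]][(tr$donor_start + 1L):
                                              tr$donor_end])
    rseg <- decode_residues(byacc[[tr$receiver]][(tr$receiver_start + 1L):
                                                 tr$receiver_end])
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(dseg), Biostrings::AAString(rseg),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = gap_open, gapExtension = gap_extend)
    out$measured_identity[i] <- Biostrings::nmatch(al) /
      (Biostrings::nmatch(al) + Biostrings::nmismatch(al))
  }
  out
}
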