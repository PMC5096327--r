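#' The indexable amino-acid alphabet
#'
#' The index is built over the 20 canonical amino acids, in NCBI matrix order.
#' Ambiguity codes (X, B, Z, U, *) and any unrecognised character are mapped to
#' a single mask code that never forms an indexed word; masked positions score
#' -1 against every residue.
#'
#' @return A single string of the 20 indexable residue letters.
#' @export
aa_alphabet <- function() "ARNDCQEGHILKMFPSTWYV"

# residues that silently map to the mask code (defined ambiguity letters)
.ambiguity_letters <- c("X", "B", "Z", "U", "*")

.alpha_size <- 20L
.mask_code <- 20L

.code_lookup <- function() {
  if (!is.null(.dbb_cache$code_lookup)) return(.dbb_cache$code_lookup)
  lut <- rep(NA_integer_, 256L)
  letters20 <- strsplit(aa_alphabet(), "")[[1]]
  lut[utf8ToInt(paste(letters20, collapse = "")) + 1L] <- seq_along(letters20) - 1L
  lut[utf8ToInt(paste(.ambiguity_letters, collapse = "")) + 1L] <- .mask_code
  .dbb_cache$code_lookup <- lut
  lut
}

#' Encode residues as integer codes
#'
#' Canonical residues map to codes 0..19 (order of [aa_alphabet()]); defined
#' ambiguity letters map silently to the mask code 20; any other character
#' also maps to 20 and is counted in the `n_unknown` attribute so callers can
#' warn. Input is uppercased first.
#'
#' @param x A single character string of residues.
#' @return Integer vector of 0-based codes with attribute `n_unknown`.
#' @export
encode_residues <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  b <- utf8ToInt(toupper(x))
  codes <- .code_lookup()[b + 1L]
  n_unknown <- sum(is.na(codes))
  codes[is.na(codes)] <- .mask_code
  attr(codes, "n_unknown") <- n_unknown
  codes
}

#' Decode integer residue codes back to a string
#'
#' The mask code renders as `X`.
#' @param codes Integer vector of 0-based codes.
#' @return A character string.
#' @export
decode_residues <- function(codes) {
  letters21 <- c(strsplit(aa_alphabet(), "")[[1]], "X")
  paste(letters21[codes + 1L], collapse = "")
}

#' Word id of a W-mer
#'
#' Words are base-20 numerals over the indexable alphabet: id =
#' sum(code_k * 20^(W-k)). Words containing a masked residue have no id.
#'
#' @param codes Integer codes (0-based) of exactly W residues, or a string.
#' @return 0-based integer word id, or `NA` if any residue is masked.
#' @export
word_id <- function(codes) {
  if (is.character(codes)) codes <- as.integer(encode_residues(codes))
  if (any(codes >= .alpha_size)) return(NA_integer_)
  id <- 0L
  for (c in codes) id <- id * .alpha_size + c
  id
}

#' Word string for a word id
#' @param id 0-based word id.
#' @param W Word length.
#' @return Character string of length W.
#' @export
word_string <- function(id, W = 3L) {
  codes <- integer(W)
  for (k in W:1) { codes[k] <- id %% .alpha_size; id <- id %/% .alpha_size }
  decode_residues(codes)
}

#' Bits needed to store block-local sequence ids
#'
#' A block of n sequences needs ceil(log2(n)) bits for its 0-based local ids;
#' partitioning a database into blocks is what keeps this width small.
#'
#' @param n_seqs Number of sequences.
#' @return Integer bit width (0 for a single sequence).
#' @export
seqid_bit_width <- function(n_seqs) {
  stopifnot(n_seqs >= 1)
  bits <- 0L
  while (2^bits < n_seqs) bits <- bits + 1L
  bits
}
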