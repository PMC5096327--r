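#' Substitution matrices over the package alphabet
#'
#' Returns a 21 x 21 integer scoring matrix in the order of [aa_alphabet()]
#' plus the mask residue. The 20 x 20 canonical part is taken from the
#' Biostrings BLOSUM data sets (or from an NCBI-format text file via
#' [read_matrix_file()]); every score involving the mask residue is -1.
#'
#' @param name One of "BLOSUM62", "BLOSUM45", "BLOSUM50", "BLOSUM80", or a
#'   21x21 matrix (passed through unchanged).
#' @return Integer matrix with attribute `matrix_name`.
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  if (is.matrix(name)) {
    stopifnot(nrow(name) == .alpha_size + 1L, ncol(name) == .alpha_size + 1L)
    return(name)
  }
  key <- paste0("mat_", name)
  if (!is.null(.dbb_cache[[key]])) return(.dbb_cache[[key]])
  if (!name %in% c("BLOSUM62", "BLOSUM45", "BLOSUM50", "BLOSUM80"))
    stop("unsupported substitution matrix: ", name)
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  full <- env[[name]]
  m <- .to_package_matrix(full, name)
  .dbb_cache[[key]] <- m
  m
}

.to_package_matrix <- function(full, name) {
  letters20 <- strsplit(aa_alphabet(), "")[[1]]
  if (!all(letters20 %in% rownames(full)))
    stop("matrix does not cover the 20 canonical residues")
  m <- matrix(-1L, .alpha_size + 1L, .alpha_size + 1L)
  m[seq_len(.alpha_size), seq_len(.alpha_size)] <-
    as.integer(full[letters20, letters20])
  rownames(m) <- colnames(m) <- c(letters20, "X")
  attr(m, "matrix_name") <- name
  storage.mode(m) <- "integer"
  m
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the usual whitespace-separated layout: `#` comment lines, one header
#' row of residue letters, then one row per residue. Scores for alphabet pairs
#' not present in the file, and all mask scores, are -1.
#'
#' @param path Path to the matrix file.
#' @param name Name recorded on the returned matrix (default: file name).
#' @return Integer matrix as from [substitution_matrix()].
#' @export
read_matrix_file <- function(path, name = basename(path)) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a matrix file: ", path)
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  full <- matrix(NA_integer_, length(rows), length(header),
                 dimnames = list(vapply(rows, `[[`, "", 1L), header))
  for (i in seq_along(rows)) {
    v <- rows[[i]]
    if (length(v) != length(header) + 1L)
      stop("malformed matrix row ", i, " in ", path)
    full[i, ] <- as.integer(v[-1])
  }
  letters20 <- strsplit(aa_alphabet(), "")[[1]]
  missing <- setdiff(letters20, intersect(rownames(full), colnames(full)))
  if (length(missing))
    stop("matrix file lacks residues: ", paste(missing, collapse = ", "))
  .to_package_matrix(full, name)
}
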