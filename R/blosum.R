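#' Substitution matrices in NCBI text format
#'
#' `read_substitution_matrix()` parses a matrix file in the NCBI format
#' used by BLAST distributions: `#` comment lines, a header row of residue
#' codes, then one row per residue with integer scores. The matrix must be
#' symmetric and cover the 20 standard amino acids (extra codes such as
#' B/Z/X/* are kept and usable). `blosum80()` returns the packaged NCBI
#' BLOSUM80 matrix (matblas build, 1/3-bit units).
#'
#' @param path path to an NCBI-format matrix file
#' @return an integer matrix with residue dimnames, class
#'   `substitution_matrix`
#' @examples
#' m <- blosum80()
#' blosum_score("L", "P", m)
#' @export
read_substitution_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not an NCBI matrix file: ", path)
  alphabet <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n <- length(alphabet)
  body <- strsplit(trimws(lines[-1L]), "\\s+")
  if (length(body) != n) stop("matrix body has ", length(body),
                              " rows for ", n, " header columns")
  scores <- matrix(NA_integer_, n, n, dimnames = list(alphabet, alphabet))
  for (i in seq_len(n)) {
    row <- body[[i]]
    if (length(row) != n + 1L || row[1L] != alphabet[i])
      stop("malformed matrix row ", i)
    scores[i, ] <- as.integer(row[-1L])
  }
  if (anyNA(scores)) stop("non-integer scores in matrix file")
  if (!isTRUE(all.equal(scores, t(scores)))) stop("matrix is not symmetric")
  std <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]
  if (!all(std %in% alphabet))
    stop("matrix must cover the 20 standard amino acids")
  structure(scores, class = c("substitution_matrix", class(scores)))
}

#' @rdname read_substitution_matrix
#' @export
blosum80 <- function() {
  read_substitution_matrix(system.file("extdata", "BLOSUM80.txt",
                                       package = "ConStructOTOF"))
}

#' Substitution score lookup
#'
#' Looks up the substitution score for replacing residue `ref` with `alt`
#' (one-letter codes; vectorised). Scores are symmetric by construction of
#' the matrix.
#'
#' @param ref,alt one-letter amino-acid codes
#' @param matrix a [read_substitution_matrix()] matrix; defaults to the
#'   packaged BLOSUM80
#' @return integer vector of scores
#' @export
blosum_score <- function(ref, alt, matrix = blosum80()) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  bad <- unique(c(ref, alt)[!c(ref, alt) %in% rownames(matrix)])
  if (length(bad)) stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  as.integer(matrix[cbind(ref, alt)])
}
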