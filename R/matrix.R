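## Residue alphabet used throughout: the 20 standard amino acids, 'X' for
## unknown/non-standard residues, and '*' for terminal padding of peptide
## windows.  '*' scores 0 against every symbol so that truncation at a
## protein terminus neither rewards nor penalizes a peptide.

#' Amino-acid alphabet used by the scoring machinery
#'
#' The 20 standard residues in BLOSUM order, plus \code{"X"} (unknown
#' residue, scored through the BLOSUM62 X row) and \code{"*"} (terminal
#' padding, scored 0 against everything).
#'
#' @return Character vector of length 22.
#' @export
aa_alphabet <- function() AA_ALPHABET_

AA_ALPHABET_ <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V",
                  "X", "*")

AA_STANDARD_ <- AA_ALPHABET_[1:20]

## BLOSUM62 (half-bit scores), 20 standard residues plus the X row, in the
## canonical publication order.  The padding symbol '*' is appended as a
## zero row/column: padding is neutral, not penalized as in alignment use.
BLOSUM62_BASE_ <- local({
  aa21 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")
  v <- c(
    4, -1, -2, -2,  0, -1, -1,  0, -2, -1, -1, -1, -1, -2, -1,  1,  0, -3, -2,  0, -1,
   -1,  5,  0, -2, -3,  1,  0, -2,  0, -3, -2,  2, -1, -3, -2, -1, -1, -3, -2, -3, -1,
   -2,  0,  6,  1, -3,  0,  0,  0,  1, -3, -3,  0, -2, -3, -2,  1,  0, -4, -2, -3, -1,
   -2, -2,  1,  6, -3,  0,  2, -1, -1, -3, -4, -1, -3, -3, -1,  0, -1, -4, -3, -3, -1,
    0, -3, -3, -3,  9, -3, -4, -3, -3, -1, -1, -3, -1, -2, -3, -1, -1, -2, -2, -1, -1,
   -1,  1,  0,  0, -3,  5,  2, -2,  0, -3, -2,  1,  0, -3, -1,  0, -1, -2, -1, -2, -1,
   -1,  0,  0,  2, -4,  2,  5, -2,  0, -3, -3,  1, -2, -3, -1,  0, -1, -3, -2, -2, -1,
    0, -2,  0, -1, -3, -2, -2,  6, -2, -4, -4, -2, -3, -3, -2,  0, -2, -2, -3, -3, -1,
   -2,  0,  1, -1, -3,  0,  0, -2,  8, -3, -3, -1, -2, -1, -2, -1, -2, -2,  2, -3, -1,
   -1, -3, -3, -3, -1, -3, -3, -4, -3,  4,  2, -3,  1,  0, -3, -2, -1, -3, -1,  3, -1,
   -1, -2, -3, -4, -1, -2, -3, -4, -3,  2,  4, -2,  2,  0, -3, -2, -1, -2, -1,  1, -1,
   -1,  2,  0, -1, -3,  1,  1, -2, -1, -3, -2,  5, -1, -3, -1,  0, -1, -3, -2, -2, -1,
   -1, -1, -2, -3, -1,  0, -2, -3, -2,  1,  2, -1,  5,  0, -2, -1, -1, -1, -1,  1, -1,
   -2, -3, -3, -3, -2, -3, -3, -3, -1,  0,  0, -3,  0,  6, -4, -2, -2,  1,  3, -1, -1,
   -1, -2, -2, -1, -3, -1, -1, -2, -2, -3, -3, -1, -2, -4,  7, -1, -1, -4, -3, -2, -1,
    1, -1,  1,  0, -1,  0,  0,  0, -1, -2, -2,  0, -1, -2, -1,  4,  1, -3, -2, -2, -1,
    0, -1,  0, -1, -1, -1, -1, -2, -2, -1, -1, -1, -1, -2, -1,  1,  5, -2, -2,  0, -1,
   -3, -3, -4, -4, -2, -2, -3, -2, -2, -3, -2, -3, -1,  1, -4, -3, -2, 11,  2, -3, -1,
   -2, -2, -2, -3, -2, -1, -2, -3,  2, -1, -1, -2, -1,  3, -3, -2, -2,  2,  7, -1, -1,
    0, -3, -3, -3, -1, -2, -2, -3, -3,  3,  1, -2,  1, -1, -2, -2,  0, -3, -1,  4, -1,
   -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1)
  m21 <- matrix(v, nrow = 21, byrow = TRUE, dimnames = list(aa21, aa21))
  m <- matrix(0, 22, 22, dimnames = list(AA_ALPHABET_, AA_ALPHABET_))
  m[aa21, aa21] <- m21
  m
})

#' BLOSUM62 substitution scores over the scoring alphabet
#'
#' Returns the base substitution matrix used for peptide scoring: published
#' BLOSUM62 half-bit scores for the 20 standard residues and \code{X},
#' extended by a zero row/column for the padding symbol \code{"*"}.
#'
#' @return A symmetric 22 x 22 numeric matrix with dimnames
#'   \code{aa_alphabet()}.
#' @export
#' @examples
#' blosum62()["L", "I"]  # 2, a conserved substitution
blosum62 <- function() BLOSUM62_BASE_

#' Names of the 210 unordered standard-residue pairs
#'
#' Pair labels ("A:A", "A:R", ...) for the deltas tuned during matrix
#' mutation.  Only the 20 standard residues participate; rows for
#' \code{X} and \code{*} are never mutated.
#'
#' @return Character vector of length 210.
#' @export
matrix_pair_names <- function() {
  idx <- which(upper.tri(diag(20), diag = TRUE), arr.ind = TRUE)
  paste(AA_STANDARD_[idx[, 1]], AA_STANDARD_[idx[, 2]], sep = ":")
}

## Precomputed linear indices into the 22x22 matrix for the 210 pairs:
## one vector for the (i,j) entry and one for the mirrored (j,i) entry.
PAIR_INDEX_ <- local({
  idx <- which(upper.tri(diag(20), diag = TRUE), arr.ind = TRUE)
  list(ij = (idx[, 2] - 1L) * 22L + idx[, 1L],
       ji = (idx[, 1] - 1L) * 22L + idx[, 2L],
       diag = idx[, 1] == idx[, 2])
})

#' Build a substitution matrix from BLOSUM62 plus trained deltas
#'
#' Matrix mutation tunes an additive delta for each of the 210 unordered
#' pairs of standard residues; the result stays symmetric and leaves the
#' \code{X} and \code{*} rows at their base values.
#'
#' @param deltas Numeric vector of length 210 (order of
#'   \code{matrix_pair_names()}), or \code{NULL} for the unmutated base.
#' @return A symmetric 22 x 22 numeric matrix.
#' @export
substitution_matrix <- function(deltas = NULL) {
  m <- BLOSUM62_BASE_
  if (is.null(deltas)) return(m)
  stopifnot(is.numeric(deltas), length(deltas) == 210L)
  m[PAIR_INDEX_$ij] <- m[PAIR_INDEX_$ij] + deltas
  m[PAIR_INDEX_$ji[!PAIR_INDEX_$diag]] <-
    m[PAIR_INDEX_$ji[!PAIR_INDEX_$diag]] + deltas[!PAIR_INDEX_$diag]
  m
}

## Encode peptide strings as an integer matrix (rows = peptides, columns =
## window positions) of indices into aa_alphabet().  Unknown letters are
## mapped to 'X'.
encode_peptides <- function(peptides) {
  if (length(peptides) == 0L) {
    return(matrix(integer(0), nrow = 0, ncol = 0))
  }
  L <- unique(nchar(peptides))
  if (length(L) != 1L) {
    stop("all peptides must share one window length")
  }
  chars <- matrix(unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(peptides), ncol = L, byrow = TRUE)
  idx <- match(chars, AA_ALPHABET_)
  idx[is.na(idx)] <- match("X", AA_ALPHABET_)
  matrix(idx, nrow = length(peptides), ncol = L)
}

decode_peptides <- function(enc) {
  apply(enc, 1L, function(r) paste(AA_ALPHABET_[r], collapse = ""))
}
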