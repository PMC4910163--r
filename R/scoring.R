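## Peptide similarity and group scoring.
##
## Two peptides are compared position by position: a position counts as a
## conserved substitution when its residue pair has a positive BLOSUM62
## score.  S(A,B) is the fraction of conserved positions over the window
## length; the clustering distance is D(A,B) = 1/S(A,B), infinite when
## S(A,B) = 0.  A query is scored against a group of positive peptides as
## the mean, over the group, of the position-weighted sum of substitution
## scores.

#' Is a residue pair a conserved substitution?
#'
#' A conserved substitution is a pair with a positive substitution score
#' (BLOSUM62 by default).  Pairs involving the padding symbol \code{"*"}
#' score 0 and are therefore never conserved.
#'
#' @param a,b Single residues from \code{aa_alphabet()}.
#' @param matrix Substitution matrix (default \code{blosum62()}).
#' @return Logical scalar.
#' @export
is_conserved <- function(a, b, matrix = blosum62()) {
  if (!(a %in% rownames(matrix)) || !(b %in% rownames(matrix))) {
    stop("unknown residue symbol: ", paste(setdiff(c(a, b), rownames(matrix)),
                                           collapse = ", "))
  }
  matrix[a, b] > 0
}

#' Similarity and distance between two peptide windows
#'
#' S(A,B) is the fraction of window positions at which the aligned residue
#' pair is a conserved substitution; it ranges from 0 to 1.  The distance
#' is D(A,B) = 1/S(A,B), with D = Inf when S = 0.
#'
#' @param a,b Peptide windows (character scalars of equal length).
#' @param matrix Substitution matrix.
#' @return List with elements \code{s} (similarity) and \code{d} (distance).
#' @export
#' @examples
#' peptide_similarity("CAC", "CWC")$s  # 2/3
peptide_similarity <- function(a, b, matrix = blosum62()) {
  if (nchar(a) != nchar(b)) stop("peptide windows differ in length")
  ea <- encode_peptides(a)
  eb <- encode_peptides(b)
  cons <- matrix[cbind(ea[1, ], eb[1, ])] > 0
  s <- mean(cons)
  list(s = s, d = if (s > 0) 1 / s else Inf)
}

## Pairwise similarity matrix for encoded peptides (n x L integer matrix).
similarity_matrix <- function(enc, mat = blosum62()) {
  n <- nrow(enc)
  L <- ncol(enc)
  cons <- mat > 0
  sim <- matrix(0, n, n)
  for (pos in seq_len(L)) {
    sim <- sim + cons[enc[, pos], enc[, pos]]
  }
  sim / L
}

## --- group scoring internals ------------------------------------------
##
## For a group G of encoded positive peptides, the profile P (22 x L) has
## P[a, i] = mean over t in G of M[a, t_i].  The score of an encoded query
## q is then sum_i w_i * P[q_i, i]: scoring all queries reduces to one
## indexing pass and a matrix-vector product.

group_counts <- function(enc) {
  L <- ncol(enc)
  cnt <- matrix(0, 22L, L)
  for (pos in seq_len(L)) {
    tab <- tabulate(enc[, pos], nbins = 22L)
    cnt[, pos] <- tab
  }
  cnt
}

group_profile <- function(counts, n, matrix) {
  (matrix %*% counts) / n
}

## Scores of encoded queries (nq x L) against a profile, given weights w.
profile_scores <- function(qenc, profile, w) {
  L <- ncol(qenc)
  idx <- qenc + matrix((seq_len(L) - 1L) * 22L, nrow(qenc), L, byrow = TRUE)
  matrix(profile[idx], nrow(qenc), L) %*% w
}

## Leave-one-out scores of the group members themselves: member j is
## scored against the profile recomputed without j.
loo_member_scores <- function(enc, profile, mat, w) {
  n <- nrow(enc)
  if (n < 2L) return(rep(-Inf, n))
  L <- ncol(enc)
  idx <- enc + matrix((seq_len(L) - 1L) * 22L, n, L, byrow = TRUE)
  own <- matrix(profile[idx], n, L)          # P[q_i, i] with self included
  self <- matrix(diag(mat)[enc], n, L)       # M[q_i, q_i]
  ((n * own - self) / (n - 1)) %*% w
}

#' Score a peptide against a trained group model
#'
#' The group score is the mean over the group's positive peptides of the
#' position-weighted sum of substitution scores between the query and the
#' training peptide.
#'
#' @param query Peptide window (character scalar) of the group's window
#'   length.
#' @param group A group model (element of a fitted model's \code{groups},
#'   or a list with \code{peptides}, \code{weights} and optional
#'   \code{matrix_deltas}).
#' @return Numeric score.
#' @export
peptide_score <- function(query, group) {
  if (length(group$peptides) == 0L) stop("empty group")
  if (nchar(query) != nchar(group$peptides[[1]])) {
    stop("query window length differs from the group's window length")
  }
  m <- substitution_matrix(group$matrix_deltas)
  enc <- encode_peptides(group$peptides)
  prof <- group_profile(group_counts(enc), nrow(enc), m)
  drop(profile_scores(encode_peptides(query), prof, group$weights))
}

## Sensitivity at the cutoff achieving at least the requested specificity.
## The cutoff is the minimal observed negative score c with
## mean(neg >= c) <= 1 - sp; if none exists it sits just above max(neg).
sn_at_sp <- function(pos_scores, neg_scores, sp = 0.9) {
  cut <- cutoff_at_sp(neg_scores, sp)
  mean(pos_scores >= cut)
}

cutoff_at_sp <- function(neg_scores, sp) {
  cand <- sort(unique(neg_scores))
  n <- length(neg_scores)
  ge <- vapply(cand, function(c) sum(neg_scores >= c), numeric(1))
  ok <- ge / n <= (1 - sp) + 1e-12
  if (any(ok)) cand[which(ok)[1]] else max(neg_scores) + 1
}
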