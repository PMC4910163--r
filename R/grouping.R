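## Grouping of training sites.
##
## One modification type can be written by enzymes recognizing several
## motifs, so positives are split into groups before scoring: motif-based
## consensus / non-consensus classes for myristoylation and the two
## prenylations, and k-means clusters (custom conserved-substitution
## distance, medoid-style centroids) for palmitoylation, which has no
## reported consensus motif.

ALIPHATIC_ <- c("A", "V", "L", "I", "C", "M", "F")

#' Classify an N-myristoylation site as consensus or non-consensus
#'
#' Consensus sites follow the N-terminal MGXXXS/T signature recognized by
#' N-myristoyl transferase: the glycine at position 2 of a protein whose
#' sequence starts M-G and carries S or T at position 6.
#'
#' @param protein Protein sequence (character scalar).
#' @param position 1-based position of the glycine.
#' @return \code{"consensus"} or \code{"nonconsensus"}.
#' @export
classify_myristoylation <- function(protein, position) {
  if (substr(protein, position, position) != "G") {
    stop("position ", position, " is not a glycine")
  }
  ok <- position == 2L &&
    substr(protein, 1L, 2L) == "MG" &&
    nchar(protein) >= 6L &&
    substr(protein, 6L, 6L) %in% c("S", "T")
  if (ok) "consensus" else "nonconsensus"
}

#' Classify an S-farnesylation site by the C-terminal CAAX rule
#'
#' Consensus sites are cysteines at the fourth-to-last position of the
#' protein (the C of a C-terminal CAAX box).  An optional aliphatic filter
#' additionally requires the two following residues to be aliphatic
#' (A, V, L, I, C, M, F); it is off by default so borderline sites are
#' routed to the consensus model rather than dropped.
#'
#' @param protein Protein sequence.
#' @param position 1-based position of the cysteine.
#' @param aliphatic_filter Logical; enforce aliphatic A positions.
#' @return \code{"consensus"} or \code{"nonconsensus"}.
#' @export
classify_farnesylation <- function(protein, position, aliphatic_filter = FALSE) {
  if (substr(protein, position, position) != "C") {
    stop("position ", position, " is not a cysteine")
  }
  L <- nchar(protein)
  ok <- position == L - 3L
  if (ok && aliphatic_filter) {
    ok <- all(strsplit(substr(protein, L - 2L, L - 1L), "")[[1]] %in% ALIPHATIC_)
  }
  if (ok) "consensus" else "nonconsensus"
}

#' Classify an S-geranylgeranylation site by CAAX and CC/CXC rules
#'
#' GGTase-I recognizes a C-terminal CAAX box (cysteine fourth from the
#' end); GGTase-II recognizes Rab-type CC or CXC termini (cysteine in the
#' last two residues, or at the last and third-to-last positions).
#'
#' @inheritParams classify_farnesylation
#' @return One of \code{"consensus_caax"}, \code{"consensus_cc_cxc"},
#'   \code{"nonconsensus"}.
#' @export
classify_geranylgeranylation <- function(protein, position, aliphatic_filter = FALSE) {
  if (substr(protein, position, position) != "C") {
    stop("position ", position, " is not a cysteine")
  }
  L <- nchar(protein)
  if (position == L - 3L) {
    ok <- TRUE
    if (aliphatic_filter) {
      ok <- all(strsplit(substr(protein, L - 2L, L - 1L), "")[[1]] %in% ALIPHATIC_)
    }
    if (ok) return("consensus_caax")
  }
  last2 <- substr(protein, L - 1L, L)
  cc <- last2 == "CC" && position >= L - 1L
  cxc <- L >= 3L && substr(protein, L - 2L, L - 2L) == "C" &&
    substr(protein, L, L) == "C" && position %in% c(L - 2L, L)
  if (cc || cxc) return("consensus_cc_cxc")
  "nonconsensus"
}

classify_site <- function(protein, position, mod_type, aliphatic_filter = FALSE) {
  switch(mod_type,
         MYR = classify_myristoylation(protein, position),
         FARN = classify_farnesylation(protein, position, aliphatic_filter),
         GERA = classify_geranylgeranylation(protein, position, aliphatic_filter),
         PALM = "kmeans")
}

#' Cluster peptides by k-means under the conserved-substitution distance
#'
#' Peptides are clustered with D(A,B) = 1/S(A,B) (infinite when no
#' position is conserved).  Centroids are cluster members: after each
#' assignment pass the centroid of a cluster is updated to the member with
#' the highest average similarity to its cluster.  The best of
#' \code{restarts} seeded random initializations (by mean intra-cluster
#' similarity) is returned.  Ties break toward the lowest cluster id /
#' lowest peptide index, so results are fully reproducible.
#'
#' @param peptides Character vector of equal-length peptide windows.
#' @param k Number of clusters (1..length(peptides)).
#' @param restarts Number of random initializations.
#' @param seed Integer seed.
#' @param matrix Substitution matrix used for the similarity.
#' @return List with \code{labels} (integer cluster per peptide),
#'   \code{centroids} (peptide index per cluster) and
#'   \code{mean_intra_similarity}.
#' @export
kmeans_peptides <- function(peptides, k, restarts = 10L, seed = 1L,
                            matrix = blosum62()) {
  n <- length(peptides)
  if (k < 1L || k > n) stop("k must be in 1..", n)
  enc <- encode_peptides(peptides)
  sim <- similarity_matrix(enc, matrix)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      res <- kmeans_once(sim, k, init = sample.int(n, k))
      if (is.null(best) ||
          res$mean_intra_similarity > best$mean_intra_similarity + 1e-12) {
        best <- res
      }
    }
  })
  best
}

kmeans_once <- function(sim, k, init) {
  n <- nrow(sim)
  centroids <- sort(init)
  labels <- integer(n)
  for (iter in 1:100) {
    ## assign to the nearest centroid: max similarity = min D = 1/S;
    ## ties (incl. all-zero similarity) break to the lowest cluster id
    simc <- sim[, centroids, drop = FALSE]
    labels_new <- max.col(simc, ties.method = "first")
    ## update centroids: member with the highest average similarity to
    ## its own cluster (lowest index on ties)
    centroids_new <- centroids
    for (c in seq_len(k)) {
      members <- which(labels_new == c)
      if (length(members) == 0L) next  # keep the old centroid
      avg <- rowMeans(sim[members, members, drop = FALSE])
      centroids_new[c] <- members[which.max(avg)]
    }
    if (identical(labels_new, labels) && identical(centroids_new, centroids)) break
    labels <- labels_new
    centroids <- centroids_new
  }
  intra <- vapply(seq_len(k), function(c) {
    members <- which(labels == c)
    if (length(members) == 0L) return(NA_real_)
    mean(sim[members, members, drop = FALSE])
  }, numeric(1))
  sizes <- tabulate(labels, nbins = k)
  list(labels = labels, centroids = centroids,
       mean_intra_similarity = sum(intra * sizes, na.rm = TRUE) / sum(sizes))
}
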