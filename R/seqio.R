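## Sequence and site-annotation input/output.
##
## Proteins are held as a named character vector (names = FASTA header
## tokens, values = uppercase amino-acid sequences).  Sites are a
## data.frame with columns protein_id, position (1-based), residue,
## mod_type and evidence.  All coordinates are 1-based and inclusive.

MOD_TYPES_ <- c("PALM", "MYR", "FARN", "GERA")
EVIDENCE_ <- c("experimental", "predicted")

#' Modification types supported by the predictor
#'
#' @return Character vector: \code{"PALM"} (S-palmitoylation),
#'   \code{"MYR"} (N-myristoylation), \code{"FARN"} (S-farnesylation),
#'   \code{"GERA"} (S-geranylgeranylation).
#' @export
mod_types <- function() MOD_TYPES_

#' Target residue of a modification type
#'
#' N-myristoylation modifies glycine; the three cysteine-directed types
#' (palmitoylation and the two prenylations) modify cysteine.
#'
#' @param mod_type One or more of \code{mod_types()}.
#' @return Character vector of single residues ("G" or "C").
#' @export
mod_residue <- function(mod_type) {
  stopifnot(all(mod_type %in% MOD_TYPES_))
  ifelse(mod_type == "MYR", "G", "C")
}

normalize_sequence <- function(x) {
  x <- toupper(gsub("[*-]", "", x))
  chars <- strsplit(x, "", fixed = TRUE)
  vapply(chars, function(cc) {
    cc[!(cc %in% AA_STANDARD_)] <- "X"
    paste(cc, collapse = "")
  }, character(1))
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased, alignment characters (\code{*}, \code{-})
#' stripped, and non-standard letters mapped to \code{X}.  Record ids are
#' the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of protein sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA ids: ", paste(unique(dup), collapse = ", "))
  }
  seqs <- normalize_sequence(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for id: ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(proteins, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(proteins), path)
  invisible(path)
}

#' Extract the peptide window PSP(m, n) around a residue
#'
#' Returns the candidate residue flanked by \code{m} residues upstream and
#' \code{n} downstream; positions beyond the protein termini are padded
#' with \code{"*"}.
#'
#' @param protein A single protein sequence (character scalar).
#' @param position 1-based position of the central residue.
#' @param m,n Number of upstream / downstream flanking residues.
#' @return Character scalar of length m + n + 1.
#' @export
#' @examples
#' extract_window("MGCIKSK", 2, 3, 3)  # "**MGCIK"
extract_window <- function(protein, position, m, n) {
  L <- nchar(protein)
  if (length(position) != 1L || is.na(position) || position < 1L || position > L) {
    stop("position ", position, " out of range 1..", L)
  }
  lo <- position - m
  hi <- position + n
  pad_l <- max(0L, 1L - lo)
  pad_r <- max(0L, hi - L)
  core <- substr(protein, max(1L, lo), min(L, hi))
  paste0(strrep("*", pad_l), core, strrep("*", pad_r))
}

## Vectorized window extraction for many (protein, position) pairs.
extract_windows <- function(proteins, protein_id, position, m, n) {
  mapply(function(id, pos) extract_window(proteins[[id]], pos, m, n),
         protein_id, position, USE.NAMES = FALSE)
}

#' Enumerate candidate residues of a protein
#'
#' All 1-based positions carrying the given residue, in ascending order.
#' These are the candidate sites of a modification type: annotated ones
#' are positives, all remaining ones negatives.
#'
#' @param protein A single protein sequence.
#' @param residue \code{"C"} or \code{"G"}.
#' @return Integer vector of positions (possibly empty).
#' @export
enumerate_candidates <- function(protein, residue) {
  stopifnot(residue %in% c("C", "G"))
  which(strsplit(protein, "", fixed = TRUE)[[1]] == residue)
}

validate_sites <- function(sites, proteins) {
  problems <- character(0)
  for (i in seq_len(nrow(sites))) {
    row <- sites[i, ]
    where <- paste0("site row ", i, " (", row$protein_id, ":", row$position, ")")
    if (!(row$mod_type %in% MOD_TYPES_)) {
      problems <- c(problems, paste0(where, ": unknown mod_type '", row$mod_type, "'"))
      next
    }
    if (!(row$protein_id %in% names(proteins))) {
      problems <- c(problems, paste0(where, ": unknown protein id"))
      next
    }
    seq <- proteins[[row$protein_id]]
    if (is.na(row$position) || row$position < 1L || row$position > nchar(seq)) {
      problems <- c(problems, paste0(where, ": position out of range"))
      next
    }
    actual <- substr(seq, row$position, row$position)
    if (actual != row$residue) {
      problems <- c(problems, paste0(
        where, ": residue mismatch, annotation says ", row$residue,
        " but sequence has ", actual))
    }
    if (row$residue != mod_residue(row$mod_type)) {
      problems <- c(problems, paste0(
        where, ": ", row$mod_type, " requires residue ",
        mod_residue(row$mod_type)))
    }
  }
  if (length(problems) > 0L) {
    stop("invalid site annotations:\n  ", paste(problems, collapse = "\n  "))
  }
  invisible(sites)
}

#' Read site annotations from a tab-separated file
#'
#' Expects a header line and columns \code{protein_id}, \code{position}
#' (1-based), \code{residue}, \code{mod_type} and optionally
#' \code{evidence}.  Every row is validated against the sequences: the
#' position must carry the annotated residue, and the residue must match
#' the modification chemistry (G for MYR, C otherwise).
#'
#' @param path Path to the TSV file.
#' @param proteins Named character vector of sequences (see
#'   \code{\link{read_fasta}}).
#' @return A data.frame of validated sites.
#' @export
read_sites <- function(path, proteins) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  need <- c("protein_id", "position", "residue", "mod_type")
  if (!all(need %in% names(df))) {
    stop("site table must have columns ", paste(need, collapse = ", "))
  }
  if (!("evidence" %in% names(df))) df$evidence <- "experimental"
  if (!all(df$evidence %in% EVIDENCE_)) {
    stop("evidence must be one of ", paste(EVIDENCE_, collapse = ", "))
  }
  df$position <- as.integer(df$position)
  df <- df[, c("protein_id", "position", "residue", "mod_type", "evidence")]
  validate_sites(df, proteins)
  df
}

#' Write site annotations to a tab-separated file
#'
#' @param sites Data.frame as returned by \code{\link{read_sites}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Drop homologous proteins given a pre-clustered id list
#'
#' Redundancy removal (e.g. CD-HIT at 40\% identity) is delegated to
#' external tools; this hook keeps only the representative ids that such a
#' tool emitted, together with their sites.
#'
#' @param proteins Named character vector of sequences.
#' @param sites Site data.frame.
#' @param keep_ids Character vector of representative protein ids.
#' @return List with filtered \code{proteins} and \code{sites}.
#' @export
filter_redundant <- function(proteins, sites, keep_ids) {
  keep <- names(proteins) %in% keep_ids
  list(proteins = proteins[keep],
       sites = sites[sites$protein_id %in% names(proteins)[keep], , drop = FALSE])
}
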