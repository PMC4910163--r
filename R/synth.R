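## Seeded synthetic data with planted motif structure.
##
## The generator emulates the study conditions of a motif-driven site
## predictor: every synthetic protein carries one planted positive site of
## the requested type, flanked by a position-specific signal whose
## per-position consensus probability is the signal strength, over a
## uniform background of the 20 standard residues.  Myristoylation
## positives start with M-G and carry S/T at position 6; prenylation
## positives sit in C-terminal CAAX or CC/CXC contexts with an upstream
## signal; palmitoylation positives embed one of three distinct 7-residue
## family consensus patterns around an internal cysteine.  All remaining
## cysteines / glycines are negatives.

## Planted palmitoylation family consensus 7-mers (center = modified C).
## Chosen so that non-center positions are mutually non-conserved in
## BLOSUM62, keeping the three families separable.
PALM_FAMILIES_ <- c("GKLCSKF", "PIRCRDG", "EDNCYAH")

## Upstream signal (positions -5..-1) and C-terminal contexts for the
## prenylation types.
FARN_UPSTREAM_ <- c("K", "K", "S", "K", "K")
GERA_UPSTREAM_ <- c("S", "K", "D", "G", "K")
MYR_SIGNAL_ <- c("N", "S", "K", "S", "K")  # protein positions 3..7
CAAX_ALIPHATIC_ <- c("V", "I", "L")
CAAX_X_ <- c("M", "S", "Q", "A")

#' Specification of a synthetic motif-planted dataset
#'
#' @param mod_type Modification type whose motif is planted.
#' @param n_pos Number of positive sites (one per protein).
#' @param length_range Protein length range (uniform draw).
#' @param signal_strength Per-position probability, in [0.5, 1], that a
#'   signal position carries its consensus residue rather than a random
#'   one.
#' @param background Residue frequencies of the background (default
#'   uniform over the 20 standard residues).
#' @param seed Integer seed; generation is byte-reproducible.
#' @return List of class \code{"synth_spec"}.
#' @export
synth_spec <- function(mod_type, n_pos = 60L, length_range = c(80L, 160L),
                       signal_strength = 0.8, background = NULL,
                       seed = 1L) {
  stopifnot(mod_type %in% MOD_TYPES_,
            signal_strength >= 0.5, signal_strength <= 1,
            length_range[1] >= 20L, n_pos >= 1L)
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA_STANDARD_)
  }
  stopifnot(abs(sum(background) - 1) < 1e-8)
  structure(list(mod_type = mod_type, n_pos = as.integer(n_pos),
                 length_range = as.integer(length_range),
                 signal_strength = signal_strength,
                 background = background, seed = as.integer(seed)),
            class = "synth_spec")
}

draw_background <- function(n, background) {
  sample(names(background), n, replace = TRUE, prob = background)
}

maybe_consensus <- function(consensus, strength, background) {
  hit <- stats::runif(length(consensus)) < strength
  out <- draw_background(length(consensus), background)
  out[hit] <- consensus[hit]
  out
}

#' Generate a synthetic motif-planted dataset
#'
#' One positive site per protein, plus the naturally occurring background
#' cysteines / glycines as negatives (at least two decoy candidate
#' residues are guaranteed per protein).  The ground truth is returned in
#' the same site-table dialect that \code{\link{read_sites}} consumes.
#'
#' @param spec A \code{\link{synth_spec}}.
#' @return List with \code{proteins} (named character vector) and
#'   \code{sites} (ground-truth data.frame).
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  res <- with_seed(spec$seed, {
    proteins <- character(spec$n_pos)
    rows <- vector("list", spec$n_pos)
    for (i in seq_len(spec$n_pos)) {
      L <- sample(seq(spec$length_range[1], spec$length_range[2]), 1L)
      chars <- draw_background(L, spec$background)
      s <- spec$signal_strength
      if (spec$mod_type == "MYR") {
        chars[1] <- "M"
        chars[2] <- "G"
        chars[3:7] <- maybe_consensus(MYR_SIGNAL_, s, spec$background)
        pos <- 2L
      } else if (spec$mod_type == "PALM") {
        fam <- PALM_FAMILIES_[(i - 1L) %% 3L + 1L]
        pos <- sample(20:(L - 20L), 1L)
        chars[(pos - 3L):(pos + 3L)] <-
          maybe_consensus(strsplit(fam, "")[[1]], s, spec$background)
        chars[pos] <- "C"
      } else if (spec$mod_type == "FARN") {
        pos <- L - 3L
        chars[pos] <- "C"
        chars[(pos - 5L):(pos - 1L)] <-
          maybe_consensus(FARN_UPSTREAM_, s, spec$background)
        chars[L - 2L] <- maybe_one_of(CAAX_ALIPHATIC_, s, spec$background)
        chars[L - 1L] <- maybe_one_of(CAAX_ALIPHATIC_, s, spec$background)
        chars[L] <- maybe_one_of(CAAX_X_, s, spec$background)
      } else {  # GERA: alternate CAAX and CC/CXC termini
        if (i %% 2L == 1L) {
          pos <- L - 3L
          chars[pos] <- "C"
          chars[L - 2L] <- maybe_one_of(CAAX_ALIPHATIC_, s, spec$background)
          chars[L - 1L] <- maybe_one_of(CAAX_ALIPHATIC_, s, spec$background)
          chars[L] <- maybe_one_of(CAAX_X_, s, spec$background)
        } else {
          pos <- L
          chars[L] <- "C"
          if (i %% 4L == 0L) chars[L - 2L] <- "C" else chars[L - 1L] <- "C"
        }
        chars[(pos - 7L):(pos - 3L)] <-
          maybe_consensus(GERA_UPSTREAM_, s, spec$background)
        chars[pos] <- "C"
      }
      residue <- mod_residue(spec$mod_type)
      ## guarantee decoy candidate residues away from the planted site
      decoy_ok <- setdiff(which(chars == residue), pos)
      need <- 2L - length(decoy_ok)
      if (need > 0L) {
        free <- setdiff(10:(L - 10L),
                        c(pos, (pos - 7L):(pos + 7L), which(chars == residue)))
        chars[free[sample.int(length(free), need)]] <- residue
      }
      proteins[i] <- paste(chars, collapse = "")
      rows[[i]] <- data.frame(protein_id = sprintf("SYN%s_%03d", spec$mod_type, i),
                              position = pos, residue = residue,
                              mod_type = spec$mod_type,
                              evidence = "experimental",
                              stringsAsFactors = FALSE)
    }
    names(proteins) <- sprintf("SYN%s_%03d", spec$mod_type, seq_len(spec$n_pos))
    list(proteins = proteins, sites = do.call(rbind, rows))
  })
  validate_sites(res$sites, res$proteins)
  res
}

maybe_one_of <- function(choices, strength, background) {
  if (stats::runif(1) < strength) {
    choices[sample.int(length(choices), 1L)]
  } else {
    draw_background(1L, background)
  }
}

#' Generate a null library for crosstalk calibration
#'
#' Sites of the four types are assigned independently and uniformly over
#' the candidate residues (each cysteine / glycine is modified by each
#' applicable type with probability \code{site_rate}), so every crosstalk
#' test's null hypothesis holds by construction.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Protein length range.
#' @param site_rate Per-candidate, per-type modification probability.
#' @param seed Integer seed.
#' @return A \code{"lipid_library"}.
#' @export
synth_null_library <- function(n_proteins = 60L, length_range = c(100L, 150L),
                               site_rate = 0.15, seed = 1L) {
  with_seed(seed, {
    background <- stats::setNames(rep(1 / 20, 20), AA_STANDARD_)
    proteins <- stats::setNames(vapply(seq_len(n_proteins), function(i) {
      L <- sample(seq(length_range[1], length_range[2]), 1L)
      paste(draw_background(L, background), collapse = "")
    }, character(1)), sprintf("NULL_%03d", seq_len(n_proteins)))
    rows <- list()
    for (id in names(proteins)) {
      for (type in MOD_TYPES_) {
        residue <- mod_residue(type)
        cand <- enumerate_candidates(proteins[[id]], residue)
        hit <- cand[stats::runif(length(cand)) < site_rate]
        if (length(hit) > 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            protein_id = id, position = hit, residue = residue,
            mod_type = type, evidence = "experimental",
            stringsAsFactors = FALSE)
        }
      }
    }
    sites <- do.call(rbind, rows)
    structure(list(proteins = proteins, sites = sites),
              class = "lipid_library")
  })
}
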