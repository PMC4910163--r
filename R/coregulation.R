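## Dual-lipid co-regulation statistics.
##
## Over an annotated library (experimental sites merged with
## high-stringency predictions), three questions are asked for pairs of
## modification types: do the two types co-occur on the same proteins
## (protein-level chi-square), do sites of one type sit near sites of the
## other (flanking-window chi-square at (5,5) / (10,10) / (15,15)), and do
## two cysteine-directed types hit the very same cysteine (upper-tail
## hypergeometric test with an enrichment ratio)?  Significance values are
## reported as -ln(p), so 0.05 and 0.01 correspond to 2.99 and 4.61.

#' Significance transform of a p-value
#'
#' \code{-ln(p)}.  A p-value of 0.05 maps to 2.99 (two decimals) and 0.01
#' to 4.61.  Non-positive p (or p below the double floor) returns the
#' capped sentinel \code{-ln(.Machine$double.xmin)} with attribute
#' \code{capped = TRUE}.
#'
#' @param p A p-value in (0, 1].
#' @return Numeric significance.
#' @export
significance <- function(p) {
  cap <- -log(.Machine$double.xmin)
  if (is.na(p)) return(NA_real_)
  if (p <= .Machine$double.xmin) {
    return(structure(cap, capped = TRUE))
  }
  -log(p)
}

#' Merge experimental annotations with high-stringency predictions
#'
#' Runs each available model over the library proteins at the requested
#' stringency, merges predicted with experimental sites, and removes
#' duplicates on (protein, position, type); experimental evidence wins.
#'
#' @param proteins Named character vector of sequences.
#' @param sites Experimental site annotations (validated data.frame).
#' @param models Named list of fitted \code{"lipid_model"} objects (names
#'   from \code{mod_types()}); types without a model are kept as
#'   experimental-only, with a warning.
#' @param stringency Prediction stringency (default \code{"high"}).
#' @return List of class \code{"lipid_library"} with \code{proteins} and
#'   \code{sites}.
#' @export
build_library <- function(proteins, sites, models = list(),
                          stringency = "high") {
  missing <- setdiff(MOD_TYPES_, names(models))
  if (length(models) > 0L && length(missing) > 0L) {
    warning("no model for ", paste(missing, collapse = ", "),
            "; those types keep experimental annotations only")
  }
  pred <- lapply(models, function(m) {
    p <- predict(m, proteins, stringency = stringency)
    if (nrow(p) == 0L) return(NULL)
    data.frame(protein_id = p$protein_id, position = p$position,
               residue = substr(p$peptide, m$window[["m"]] + 1L,
                                m$window[["m"]] + 1L),
               mod_type = p$mod_type, evidence = "predicted",
               stringsAsFactors = FALSE)
  })
  all <- rbind(sites[, c("protein_id", "position", "residue",
                         "mod_type", "evidence")],
               do.call(rbind, pred))
  ## dedup on (protein, position, type); experimental rows first so they win
  all <- all[order(all$evidence != "experimental"), , drop = FALSE]
  key <- paste(all$protein_id, all$position, all$mod_type)
  all <- all[!duplicated(key), , drop = FALSE]
  rownames(all) <- NULL
  structure(list(proteins = proteins, sites = all), class = "lipid_library")
}

#' @export
print.lipid_library <- function(x, ...) {
  cat("Annotated lipid-modification library:",
      length(x$proteins), "proteins,", nrow(x$sites), "sites\n")
  print(table(x$sites$mod_type, x$sites$evidence))
  invisible(x)
}

crosstalk_result <- function(pair, test, statistic, p, window = NULL,
                             enrichment_ratio = NULL, table = NULL,
                             degenerate = FALSE) {
  structure(list(pair = pair, test = test, window = window,
                 statistic = statistic, p = p,
                 significance = significance(p),
                 enrichment_ratio = enrichment_ratio,
                 table = table, degenerate = degenerate),
            class = "crosstalk_result")
}

#' @export
print.crosstalk_result <- function(x, ...) {
  cat(sprintf("%s crosstalk %s ~ %s%s: statistic = %.4g, p = %.4g, significance = %.2f%s\n",
              x$test, x$pair[1], x$pair[2],
              if (!is.null(x$window)) sprintf(" at (%d,%d)", x$window[1], x$window[2]) else "",
              x$statistic, x$p, x$significance,
              if (!is.null(x$enrichment_ratio))
                sprintf(", enrichment = %.2f", x$enrichment_ratio) else ""))
  invisible(x)
}

## Pearson chi-square on a 2x2 table, df = 1, no continuity correction by
## default.  Degenerate margins are reported as p = 1.
chisq_2x2 <- function(tab, correct = FALSE) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(statistic = 0, p = 1, degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value),
       degenerate = FALSE)
}

#' Protein-level co-occurrence test for two modification types
#'
#' Tests, over all library proteins, whether carrying a site of one type
#' is independent of carrying a site of the other (2x2 Pearson chi-square,
#' df = 1, no continuity correction).
#'
#' @param lib A \code{"lipid_library"}.
#' @param type_a,type_b Two modification types.
#' @param correct Apply the Yates continuity correction (off by default).
#' @return A \code{"crosstalk_result"}.
#' @export
cooccurrence_test <- function(lib, type_a, type_b, correct = FALSE) {
  stopifnot(type_a %in% MOD_TYPES_, type_b %in% MOD_TYPES_)
  ids <- names(lib$proteins)
  has_a <- ids %in% lib$sites$protein_id[lib$sites$mod_type == type_a]
  has_b <- ids %in% lib$sites$protein_id[lib$sites$mod_type == type_b]
  tab <- matrix(c(sum(has_a & has_b), sum(has_a & !has_b),
                  sum(!has_a & has_b), sum(!has_a & !has_b)),
                2, 2, byrow = TRUE,
                dimnames = list(A = c("yes", "no"), B = c("yes", "no")))
  res <- chisq_2x2(tab, correct)
  crosstalk_result(c(type_a, type_b), "cooccurrence", res$statistic, res$p,
                   table = tab, degenerate = res$degenerate)
}

#' Spatial proximity test for two modification types
#'
#' For every candidate residue of type A's amino acid across the library,
#' asks whether at least one B site lies within the flanking window
#' (excluding the residue's own position), and tests A-modified against
#' unmodified candidate residues with a 2x2 chi-square.
#'
#' @param lib A \code{"lipid_library"}.
#' @param type_a,type_b Two different modification types.
#' @param window Flanking region, e.g. \code{c(5, 5)}, \code{c(10, 10)} or
#'   \code{c(15, 15)}.
#' @param correct Yates correction flag.
#' @return A \code{"crosstalk_result"}.
#' @export
proximity_test <- function(lib, type_a, type_b, window = c(10, 10),
                           correct = FALSE) {
  stopifnot(type_a %in% MOD_TYPES_, type_b %in% MOD_TYPES_)
  if (type_a == type_b) stop("proximity test needs two different types")
  residue <- mod_residue(type_a)
  a_sites <- lib$sites[lib$sites$mod_type == type_a, , drop = FALSE]
  if (nrow(a_sites) == 0L) {
    stop("no ", type_a, " sites in the library (pair ", type_a, "-", type_b, ")")
  }
  b_sites <- lib$sites[lib$sites$mod_type == type_b, , drop = FALSE]
  a_key <- paste(a_sites$protein_id, a_sites$position)
  counts <- matrix(0, 2, 2, dimnames = list(
    A = c("modified", "unmodified"), near_B = c("yes", "no")))
  for (id in names(lib$proteins)) {
    cand <- enumerate_candidates(lib$proteins[[id]], residue)
    if (length(cand) == 0L) next
    bpos <- b_sites$position[b_sites$protein_id == id]
    is_a <- paste(id, cand) %in% a_key
    near <- vapply(cand, function(p) {
      any(bpos != p & bpos >= p - window[1] & bpos <= p + window[2])
    }, logical(1))
    counts[1, 1] <- counts[1, 1] + sum(is_a & near)
    counts[1, 2] <- counts[1, 2] + sum(is_a & !near)
    counts[2, 1] <- counts[2, 1] + sum(!is_a & near)
    counts[2, 2] <- counts[2, 2] + sum(!is_a & !near)
  }
  res <- chisq_2x2(counts, correct)
  crosstalk_result(c(type_a, type_b), "proximity", res$statistic, res$p,
                   window = as.integer(window), table = counts,
                   degenerate = res$degenerate)
}

#' In-situ crosstalk test between cysteine-directed modifications
#'
#' Tests whether a prenylation type is enriched on the very cysteines
#' carrying another cysteine-directed modification, with an upper-tail
#' hypergeometric test.  The population is every cysteine of library
#' proteins carrying at least one lipid annotation; K cysteines carry the
#' other type, n carry the prenyl type, k carry both.  The enrichment
#' ratio is (k/n) / (K/N).
#'
#' @param lib A \code{"lipid_library"}.
#' @param prenyl_type \code{"FARN"} or \code{"GERA"}.
#' @param other_type \code{"PALM"}, \code{"FARN"} or \code{"GERA"}.
#' @return A \code{"crosstalk_result"} with \code{enrichment_ratio}.
#' @export
insitu_test <- function(lib, prenyl_type, other_type) {
  stopifnot(prenyl_type %in% c("FARN", "GERA"),
            other_type %in% c("PALM", "FARN", "GERA"),
            prenyl_type != other_type)
  annotated <- unique(lib$sites$protein_id)
  if (length(annotated) == 0L) stop("library has no annotated proteins")
  cys <- do.call(rbind, lapply(annotated, function(id) {
    p <- enumerate_candidates(lib$proteins[[id]], "C")
    if (length(p) == 0L) return(NULL)
    data.frame(protein_id = id, position = p, stringsAsFactors = FALSE)
  }))
  if (is.null(cys) || nrow(cys) == 0L) stop("no cysteines in annotated proteins")
  key <- paste(cys$protein_id, cys$position)
  key_of <- function(type) {
    s <- lib$sites[lib$sites$mod_type == type, , drop = FALSE]
    paste(s$protein_id, s$position)
  }
  in_other <- key %in% key_of(other_type)
  in_prenyl <- key %in% key_of(prenyl_type)
  N <- length(key)
  K <- sum(in_other)
  n <- sum(in_prenyl)
  k <- sum(in_other & in_prenyl)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  enr <- if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_
  crosstalk_result(c(prenyl_type, other_type), "insitu",
                   statistic = k, p = p, enrichment_ratio = enr,
                   table = c(N = N, K = K, n = n, k = k))
}

#' Run the full crosstalk panel over a library
#'
#' Co-occurrence for all six unordered type pairs, proximity at the three
#' standard windows for pairs where both types have sites, and the in-situ
#' tests among the cysteine-directed types.  Pairs where either type has
#' no sites are reported as not applicable (NA statistics).
#'
#' @param lib A \code{"lipid_library"}.
#' @param windows List of proximity windows.
#' @return Data.frame, one row per test.
#' @export
crosstalk_panel <- function(lib, windows = list(c(5, 5), c(10, 10), c(15, 15))) {
  pairs <- utils::combn(MOD_TYPES_, 2, simplify = FALSE)
  present <- table(factor(lib$sites$mod_type, levels = MOD_TYPES_))
  row_of <- function(r) {
    data.frame(test = r$test, type_a = r$pair[1], type_b = r$pair[2],
               window = if (is.null(r$window)) NA_integer_ else r$window[1],
               statistic = r$statistic, p = r$p,
               significance = as.numeric(r$significance),
               enrichment_ratio = if (is.null(r$enrichment_ratio))
                 NA_real_ else r$enrichment_ratio,
               stringsAsFactors = FALSE)
  }
  na_row <- function(test, a, b, window = NA_integer_) {
    data.frame(test = test, type_a = a, type_b = b, window = window,
               statistic = NA_real_, p = NA_real_, significance = NA_real_,
               enrichment_ratio = NA_real_, stringsAsFactors = FALSE)
  }
  out <- list()
  for (pr in pairs) {
    applicable <- present[pr[1]] > 0 && present[pr[2]] > 0
    out[[length(out) + 1L]] <- if (applicable) {
      row_of(cooccurrence_test(lib, pr[1], pr[2]))
    } else na_row("cooccurrence", pr[1], pr[2])
    for (w in windows) {
      out[[length(out) + 1L]] <- if (applicable) {
        row_of(proximity_test(lib, pr[1], pr[2], w))
      } else na_row("proximity", pr[1], pr[2], w[1])
    }
  }
  for (pr in list(c("FARN", "GERA"), c("FARN", "PALM"), c("GERA", "PALM"))) {
    out[[length(out) + 1L]] <- if (present[pr[1]] > 0 && present[pr[2]] > 0) {
      row_of(insitu_test(lib, pr[1], pr[2]))
    } else na_row("insitu", pr[1], pr[2])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
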