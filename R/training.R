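## The four-stage training pipeline: site grouping, motif length selection
## (MLS), weight training (WT) and matrix mutation (MaM).
##
## Training data are the annotated sites of one modification type
## (positives) plus every other candidate residue of the same amino acid
## in the same substrate proteins (negatives).  Peptides are stored at the
## full (30, 30) window; MLS picks the effective scoring window; WT tunes
## one additive weight delta per window position; MaM tunes one additive
## delta per unordered residue pair of BLOSUM62.  WT and MaM maximize the
## leave-one-out sensitivity at 90% specificity with the aging-leader
## swarm; because the optimizer reports the best solution ever evaluated
## (and the zero-delta baseline is always evaluated first), each stage's
## objective never falls below the previous stage's.

FULL_FLANK_ <- 30L

#' Control parameters for model training
#'
#' @param seed Master integer seed; all stages derive their seeds from it.
#' @param swarm_size,max_iter,stagnation,inertia,c1,c2,lifespan,challenger_trials
#'   Swarm optimizer settings (see \code{\link{pso_control}}), shared by
#'   the WT and MaM stages.
#' @param dw_bounds Search box for per-position weight deltas; weights are
#'   \code{pmax(1 + dw, 0)}.
#' @param ds_bounds Search box for per-pair substitution-score deltas.
#' @param mls_grid Candidate (m, n) windows for motif length selection, as
#'   a two-column matrix; defaults to the square grid over
#'   \{1, 3, 5, 7, 10, 15, 20, 25, 30\}.
#' @param k_palm Number of k-means clusters for palmitoylation.
#' @param kmeans_restarts Random restarts for the peptide k-means.
#' @param sp_train Specificity at which the training objective reads the
#'   sensitivity (0.90).
#' @param sp_levels Specificity levels defining the high / medium / low
#'   prediction stringencies.
#' @param min_group Groups with fewer positives than this are merged into
#'   the non-consensus (or largest) group.
#' @param aliphatic_filter Enforce aliphatic residues in CAAX
#'   classification (off by default).
#' @return A list of class \code{"train_control"}.
#' @export
train_control <- function(seed = 1L, swarm_size = 20L, max_iter = 100L,
                          stagnation = 50L, inertia = 0.4, c1 = 2, c2 = 2,
                          lifespan = 60L, challenger_trials = 2L,
                          dw_bounds = c(-1, 1), ds_bounds = c(-4, 4),
                          mls_grid = NULL, k_palm = 3L,
                          kmeans_restarts = 10L, sp_train = 0.90,
                          sp_levels = c(high = 0.95, medium = 0.90, low = 0.85),
                          min_group = 3L, aliphatic_filter = FALSE) {
  if (is.null(mls_grid)) {
    g <- c(1L, 3L, 5L, 7L, 10L, 15L, 20L, 25L, 30L)
    mls_grid <- as.matrix(expand.grid(m = g, n = g))
  }
  structure(list(seed = as.integer(seed), swarm_size = as.integer(swarm_size),
                 max_iter = as.integer(max_iter), stagnation = stagnation,
                 inertia = inertia, c1 = c1, c2 = c2,
                 lifespan = as.integer(lifespan),
                 challenger_trials = as.integer(challenger_trials),
                 dw_bounds = dw_bounds, ds_bounds = ds_bounds,
                 mls_grid = mls_grid, k_palm = as.integer(k_palm),
                 kmeans_restarts = as.integer(kmeans_restarts),
                 sp_train = sp_train, sp_levels = sp_levels,
                 min_group = as.integer(min_group),
                 aliphatic_filter = isTRUE(aliphatic_filter)),
            class = "train_control")
}

pso_from_train <- function(control, seed) {
  pso_control(swarm_size = control$swarm_size, inertia = control$inertia,
              c1 = control$c1, c2 = control$c2, lifespan = control$lifespan,
              challenger_trials = control$challenger_trials,
              max_iter = control$max_iter, stagnation = control$stagnation,
              seed = seed)
}

#' Assemble the training set for one modification type
#'
#' Positives are the annotated sites of the type; negatives are all other
#' candidate residues (cysteine for the cysteine-directed types, glycine
#' for myristoylation) in the same substrate proteins.  Peptides are
#' extracted at the full (30, 30) window, terminus-padded with \code{"*"}.
#'
#' @param proteins Named character vector of sequences.
#' @param sites Validated site data.frame (see \code{\link{read_sites}}).
#' @param mod_type One of \code{mod_types()}.
#' @param max_negatives Optional cap on the number of negatives; if
#'   exceeded, a seeded uniform subsample is kept.
#' @param seed Seed for the negative subsample.
#' @return List of class \code{"training_set"} with \code{positives} and
#'   \code{negatives} data.frames (protein_id, position, peptide).
#' @export
build_training_set <- function(proteins, sites, mod_type,
                               max_negatives = Inf, seed = 1L) {
  stopifnot(mod_type %in% MOD_TYPES_)
  pos <- sites[sites$mod_type == mod_type, , drop = FALSE]
  if (nrow(pos) == 0L) stop("no positive sites for ", mod_type)
  residue <- mod_residue(mod_type)
  substrates <- unique(pos$protein_id)
  pos_key <- paste(pos$protein_id, pos$position)
  neg <- do.call(rbind, lapply(substrates, function(id) {
    cand <- enumerate_candidates(proteins[[id]], residue)
    keep <- !(paste(id, cand) %in% pos_key)
    if (!any(keep)) return(NULL)
    data.frame(protein_id = id, position = cand[keep],
               stringsAsFactors = FALSE)
  }))
  if (is.null(neg)) neg <- data.frame(protein_id = character(0),
                                      position = integer(0))
  if (nrow(neg) > max_negatives) {
    with_seed(seed, keep <- sort(sample.int(nrow(neg), max_negatives)))
    neg <- neg[keep, , drop = FALSE]
  }
  mk <- function(df) {
    df$peptide <- extract_windows(proteins, df$protein_id, df$position,
                                  FULL_FLANK_, FULL_FLANK_)
    rownames(df) <- NULL
    df
  }
  structure(list(mod_type = mod_type,
                 positives = mk(pos[, c("protein_id", "position")]),
                 negatives = mk(neg)),
            class = "training_set")
}

## Trim stored (30,30) peptides to an (m,n) window.
trim_windows <- function(peptides, m, n) {
  if (m > FULL_FLANK_ || n > FULL_FLANK_) {
    stop("window exceeds the stored (30, 30) context")
  }
  substr(peptides, FULL_FLANK_ + 1L - m, FULL_FLANK_ + 1L + n)
}

## Group memberships for the positives of a training set: integer labels
## plus group descriptors (id, kind).
assign_groups <- function(proteins, ts, control) {
  pos <- ts$positives
  if (ts$mod_type == "PALM") {
    km <- kmeans_peptides(pos$peptide, k = min(control$k_palm, nrow(pos)),
                          restarts = control$kmeans_restarts,
                          seed = derive_seed(control$seed, 11L))
    labels <- km$labels
    ids <- paste0("cluster", seq_len(max(labels)))
    kinds <- rep("kmeans-cluster", length(ids))
  } else {
    cls <- vapply(seq_len(nrow(pos)), function(i) {
      classify_site(proteins[[pos$protein_id[i]]], pos$position[i],
                    ts$mod_type, control$aliphatic_filter)
    }, character(1))
    ids <- unique(cls)
    ## stable order: consensus classes first, nonconsensus last
    ids <- c(sort(setdiff(ids, "nonconsensus")),
             intersect("nonconsensus", ids))
    labels <- match(cls, ids)
    kinds <- ifelse(ids == "nonconsensus", "nonconsensus", "consensus")
  }
  ## merge undersized groups into the non-consensus (or largest) group
  repeat {
    sizes <- tabulate(labels, nbins = length(ids))
    small <- which(sizes > 0L & sizes < control$min_group)
    if (length(small) == 0L || sum(sizes > 0L) <= 1L) break
    g <- small[1]
    target <- if ("nonconsensus" %in% ids[-g] &&
                  sizes[match("nonconsensus", ids)] > 0L && ids[g] != "nonconsensus") {
      match("nonconsensus", ids)
    } else {
      order(sizes, decreasing = TRUE)[ifelse(order(sizes, decreasing = TRUE)[1] == g, 2L, 1L)]
    }
    warning("group '", ids[g], "' has ", sizes[g],
            " positives; merged into '", ids[target], "'")
    labels[labels == g] <- target
  }
  keep <- sort(unique(labels))
  list(labels = match(labels, keep), ids = ids[keep], kinds = kinds[keep])
}

## --- per-group objective ------------------------------------------------
##
## Precomputed scoring context for one group: encoded member peptides and
## encoded negatives at the current window.  The objective of WT/MaM is
## the leave-one-out Sn at Sp = sp_train: members are scored against the
## group with themselves removed, negatives against the full group.
group_context <- function(member_pep, neg_pep) {
  list(enc = encode_peptides(member_pep),
       neg = encode_peptides(neg_pep),
       counts = group_counts(encode_peptides(member_pep)),
       n = length(member_pep))
}

group_objective <- function(ctx, w, mat, sp) {
  prof <- group_profile(ctx$counts, ctx$n, mat)
  pos_scores <- loo_member_scores(ctx$enc, prof, mat, w)
  neg_scores <- drop(profile_scores(ctx$neg, prof, w))
  sn_at_sp(pos_scores, neg_scores, sp)
}

#' Train per-position scoring weights for one group
#'
#' Searches additive deltas \code{dw} (one per window position, within
#' \code{dw_bounds}) with the aging-leader swarm; final weights are
#' \code{pmax(1 + dw, 0)}.  The objective is the leave-one-out sensitivity
#' of the group's positives at 90\% specificity on the negatives.  The
#' zero-delta baseline is always evaluated, so the returned objective is
#' never below it.  A zero-iteration budget returns all-one weights.
#'
#' @param group Group model list (\code{peptides}, \code{weights}, ...).
#' @param neg_pep Negative peptides at the group's window.
#' @param control A \code{\link{train_control}}.
#' @param seed Optimizer seed.
#' @return The group with updated \code{weights} and an
#'   \code{objective} attribute on the result.
#' @export
train_weights <- function(group, neg_pep, control = train_control(),
                          seed = control$seed) {
  ctx <- group_context(group$peptides, neg_pep)
  mat <- substitution_matrix(group$matrix_deltas)
  L <- nchar(group$peptides[[1]])
  baseline <- group_objective(ctx, rep(1, L), mat, control$sp_train)
  if (control$max_iter == 0L) {
    group$weights <- rep(1, L)
    attr(group, "objective") <- baseline
    return(group)
  }
  res <- alc_pso(function(dw) {
    group_objective(ctx, pmax(1 + dw, 0), mat, control$sp_train)
  }, control$dw_bounds[1], control$dw_bounds[2], d = L,
  control = pso_from_train(control, seed),
  init = matrix(0, L, 1))
  group$weights <- pmax(1 + res$par, 0)
  attr(group, "objective") <- res$value
  group
}

#' Mutate the substitution matrix for one group
#'
#' Searches additive deltas over the 210 unordered standard-residue pairs
#' of BLOSUM62 (within \code{ds_bounds}) with the same leave-one-out
#' Sn-at-90\%-Sp objective, using the group's trained weights.  Symmetry
#' is preserved by construction; a zero-iteration budget leaves BLOSUM62
#' intact.
#'
#' @inheritParams train_weights
#' @return The group with updated \code{matrix_deltas} and an
#'   \code{objective} attribute.
#' @export
mutate_matrix <- function(group, neg_pep, control = train_control(),
                          seed = control$seed) {
  ctx <- group_context(group$peptides, neg_pep)
  w <- group$weights
  baseline <- group_objective(ctx, w, substitution_matrix(group$matrix_deltas),
                              control$sp_train)
  if (control$max_iter == 0L) {
    group$matrix_deltas <- rep(0, 210)
    attr(group, "objective") <- baseline
    return(group)
  }
  res <- alc_pso(function(ds) {
    group_objective(ctx, w, substitution_matrix(ds), control$sp_train)
  }, control$ds_bounds[1], control$ds_bounds[2], d = 210L,
  control = pso_from_train(control, seed),
  init = matrix(0, 210L, 1))
  group$matrix_deltas <- res$par
  attr(group, "objective") <- res$value
  group
}

#' Select the effective motif length
#'
#' Evaluates candidate (m, n) windows by the pooled leave-one-out
#' sensitivity at 90\% specificity (all-one weights, unmutated BLOSUM62,
#' groups fixed) and returns the best; ties break toward the smaller
#' total window, then the smaller m.
#'
#' @param ts A \code{\link{build_training_set}} result.
#' @param labels Integer group label per positive.
#' @param candidates Two-column matrix of (m, n) candidates.
#' @param sp Specificity level of the objective.
#' @return Integer vector \code{c(m, n)}.
#' @export
select_motif_length <- function(ts, labels, candidates, sp = 0.90) {
  if (nrow(candidates) == 0L) stop("no window candidates")
  if (any(candidates > FULL_FLANK_)) {
    stop("window candidate exceeds the stored (30, 30) context")
  }
  obj <- vapply(seq_len(nrow(candidates)), function(i) {
    m <- candidates[i, 1]; n <- candidates[i, 2]
    sl <- pooled_loo(ts, labels, m, n)
    sn_at_sp(sl$score[sl$label == "pos"], sl$score[sl$label == "neg"], sp)
  }, numeric(1))
  total <- candidates[, 1] + candidates[, 2]
  ord <- order(-obj, total, candidates[, 1])
  as.integer(candidates[ord[1], ])
}

## Pooled leave-one-out scores at window (m,n) with unit weights and the
## base matrix: each positive is scored with itself removed from its own
## group (and against the other groups in full), each negative against all
## full groups; the site score is the maximum over groups.
pooled_loo <- function(ts, labels, m, n, weights = NULL, deltas = NULL) {
  pos_pep <- trim_windows(ts$positives$peptide, m, n)
  neg_pep <- trim_windows(ts$negatives$peptide, m, n)
  L <- m + n + 1L
  ngroups <- max(labels)
  pos_enc <- encode_peptides(pos_pep)
  neg_enc <- encode_peptides(neg_pep)
  pos_scores <- matrix(-Inf, length(pos_pep), ngroups)
  neg_scores <- matrix(-Inf, length(neg_pep), ngroups)
  for (g in seq_len(ngroups)) {
    members <- which(labels == g)
    if (length(members) == 0L) next
    w <- if (is.null(weights)) rep(1, L) else weights[[g]]
    mat <- substitution_matrix(if (is.null(deltas)) NULL else deltas[[g]])
    enc <- pos_enc[members, , drop = FALSE]
    prof <- group_profile(group_counts(enc), length(members), mat)
    neg_scores[, g] <- profile_scores(neg_enc, prof, w)
    ## members: LOO against their own group
    pos_scores[members, g] <- loo_member_scores(enc, prof, mat, w)
    ## non-members: scored against the full group
    outsiders <- which(labels != g)
    if (length(outsiders) > 0L) {
      pos_scores[outsiders, g] <-
        profile_scores(pos_enc[outsiders, , drop = FALSE], prof, w)
    }
  }
  data.frame(score = c(apply(pos_scores, 1, max), apply(neg_scores, 1, max)),
             label = rep(c("pos", "neg"),
                         c(length(pos_pep), length(neg_pep))),
             stringsAsFactors = FALSE)
}

#' Fit a lipid-modification site predictor
#'
#' Runs the four training stages in order for one modification type:
#' grouping of the positive sites (motif classes, or k-means clusters for
#' palmitoylation), motif length selection, per-position weight training
#' and substitution-matrix mutation, then calibrates high / medium / low
#' stringency score cutoffs per group from the negatives.  The fit is
#' fully deterministic given the data, seed and control settings.
#'
#' @param proteins Named character vector of sequences.
#' @param sites Validated site annotations.
#' @param mod_type One of \code{mod_types()}.
#' @param control A \code{\link{train_control}}.
#' @param max_negatives,neg_seed Optional negative subsampling (see
#'   \code{\link{build_training_set}}).
#' @return An object of class \code{"lipid_model"}.
#' @export
#' @seealso \code{\link{predict.lipid_model}}, \code{\link{loo_scores}},
#'   \code{\link{write_model}}
lipid_train <- function(proteins, sites, mod_type,
                        control = train_control(),
                        max_negatives = Inf, neg_seed = control$seed) {
  ts <- build_training_set(proteins, sites, mod_type,
                           max_negatives = max_negatives, seed = neg_seed)
  fit_stages <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("training stage '", stage, "' failed: ", conditionMessage(e))
    })
  }
  grp <- fit_stages("clustering", assign_groups(proteins, ts, control))
  win <- fit_stages("motif length selection",
                    select_motif_length(ts, grp$labels, control$mls_grid,
                                        control$sp_train))
  m <- win[1]; n <- win[2]
  pos_pep <- trim_windows(ts$positives$peptide, m, n)
  neg_pep <- trim_windows(ts$negatives$peptide, m, n)

  groups <- vector("list", length(grp$ids))
  for (g in seq_along(grp$ids)) {
    members <- which(grp$labels == g)
    group <- list(group_id = grp$ids[g], kind = grp$kinds[g],
                  peptides = pos_pep[members],
                  site_keys = paste(ts$positives$protein_id[members],
                                    ts$positives$position[members], sep = ":"),
                  weights = rep(1, m + n + 1L),
                  matrix_deltas = rep(0, 210))
    ctx <- group_context(group$peptides, neg_pep)
    obj0 <- group_objective(ctx, group$weights, blosum62(), control$sp_train)
    group <- fit_stages("weight training",
                        train_weights(group, neg_pep, control,
                                      seed = derive_seed(control$seed, 100L + g)))
    obj_wt <- attr(group, "objective")
    group <- fit_stages("matrix mutation",
                        mutate_matrix(group, neg_pep, control,
                                      seed = derive_seed(control$seed, 200L + g)))
    obj_mam <- attr(group, "objective")
    ## stringency cutoffs from the negatives against the final group model
    mat <- substitution_matrix(group$matrix_deltas)
    prof <- group_profile(ctx$counts, ctx$n, mat)
    neg_scores <- drop(profile_scores(ctx$neg, prof, group$weights))
    group$thresholds <- vapply(control$sp_levels, cutoff_at_sp,
                               numeric(1), neg_scores = neg_scores)
    group$objective_trace <- c(baseline = obj0, after_wt = obj_wt,
                               after_mam = obj_mam)
    attr(group, "objective") <- NULL
    groups[[g]] <- group
  }

  structure(list(
    version = "1.0",
    mod_type = mod_type,
    window = c(m = m, n = n),
    groups = groups,
    sp_levels = control$sp_levels,
    control = control,
    seed = control$seed,
    n_positives = nrow(ts$positives),
    n_negatives = nrow(ts$negatives),
    data_checksum = dataset_checksum(proteins, sites)
  ), class = "lipid_model")
}

## Scores of arbitrary query peptides (already at the model window)
## against every group of a model: matrix (n queries x n groups).
model_group_scores <- function(model, peptides) {
  enc <- encode_peptides(peptides)
  vapply(model$groups, function(g) {
    mat <- substitution_matrix(g$matrix_deltas)
    genc <- encode_peptides(g$peptides)
    prof <- group_profile(group_counts(genc), length(g$peptides), mat)
    drop(profile_scores(enc, prof, g$weights))
  }, numeric(length(peptides)))
}

#' Predict lipid-modification sites on new proteins
#'
#' Every candidate residue of the model's type (cysteine or glycine) is
#' scored against all groups; a site is reported when its score reaches
#' the group cutoff at the requested stringency in at least one group (the
#' best-scoring group relative to its cutoff is reported).
#'
#' @param object A fitted \code{"lipid_model"}.
#' @param proteins Named character vector of sequences.
#' @param stringency \code{"high"}, \code{"medium"} or \code{"low"}
#'   (specificity 0.95 / 0.90 / 0.85 by default).
#' @param ... Unused.
#' @return Data.frame with columns protein_id, position, peptide,
#'   mod_type, group, score, cutoff.
#' @export
predict.lipid_model <- function(object, proteins,
                                stringency = c("medium", "high", "low"),
                                ...) {
  stringency <- match.arg(stringency)
  residue <- mod_residue(object$mod_type)
  m <- object$window[["m"]]; n <- object$window[["n"]]
  empty <- data.frame(protein_id = character(0), position = integer(0),
                      peptide = character(0), mod_type = character(0),
                      group = character(0), score = numeric(0),
                      cutoff = numeric(0), stringsAsFactors = FALSE)
  cand <- do.call(rbind, lapply(names(proteins), function(id) {
    if (nchar(proteins[[id]]) < 1L) {
      warning("skipping empty sequence ", id)
      return(NULL)
    }
    p <- enumerate_candidates(proteins[[id]], residue)
    if (length(p) == 0L) return(NULL)
    data.frame(protein_id = id, position = p, stringsAsFactors = FALSE)
  }))
  if (is.null(cand) || nrow(cand) == 0L) return(empty)
  cand$peptide <- extract_windows(proteins, cand$protein_id, cand$position, m, n)
  scores <- model_group_scores(object, cand$peptide)
  scores <- matrix(scores, nrow = nrow(cand))
  cuts <- vapply(object$groups, function(g) g$thresholds[[stringency]],
                 numeric(1))
  rel <- sweep(scores, 2L, cuts, "-")
  best <- max.col(rel, ties.method = "first")
  sel <- rel[cbind(seq_len(nrow(cand)), best)] >= 0
  if (!any(sel)) return(empty)
  out <- cand[sel, , drop = FALSE]
  out$mod_type <- object$mod_type
  out$group <- vapply(object$groups, `[[`, character(1), "group_id")[best[sel]]
  out$score <- scores[cbind(which(sel), best[sel])]
  out$cutoff <- cuts[best[sel]]
  rownames(out) <- NULL
  out
}

#' @export
print.lipid_model <- function(x, ...) {
  cat("Group-based lipid-modification site model\n")
  cat("  type:      ", x$mod_type, "\n")
  cat("  window:    (", x$window[["m"]], ",", x$window[["n"]], ")\n")
  cat("  groups:    ", paste0(vapply(x$groups, `[[`, character(1), "group_id"),
                              " (n=", vapply(x$groups, function(g)
                                length(g$peptides), integer(1)), ")",
                              collapse = ", "), "\n")
  cat("  training:  ", x$n_positives, "positives /", x$n_negatives,
      "negatives, seed", x$seed, "\n")
  invisible(x)
}

#' @export
summary.lipid_model <- function(object, ...) {
  g <- data.frame(
    group = vapply(object$groups, `[[`, character(1), "group_id"),
    kind = vapply(object$groups, `[[`, character(1), "kind"),
    n = vapply(object$groups, function(g) length(g$peptides), integer(1)),
    sn_baseline = vapply(object$groups, function(g)
      g$objective_trace[["baseline"]], numeric(1)),
    sn_after_wt = vapply(object$groups, function(g)
      g$objective_trace[["after_wt"]], numeric(1)),
    sn_after_mam = vapply(object$groups, function(g)
      g$objective_trace[["after_mam"]], numeric(1)),
    cutoff_high = vapply(object$groups, function(g)
      g$thresholds[["high"]], numeric(1)),
    cutoff_medium = vapply(object$groups, function(g)
      g$thresholds[["medium"]], numeric(1)),
    cutoff_low = vapply(object$groups, function(g)
      g$thresholds[["low"]], numeric(1)),
    stringsAsFactors = FALSE)
  out <- list(mod_type = object$mod_type, window = object$window,
              groups = g, n_positives = object$n_positives,
              n_negatives = object$n_negatives)
  class(out) <- "summary.lipid_model"
  out
}

#' @export
print.summary.lipid_model <- function(x, ...) {
  cat("Model for", x$mod_type, "at window (",
      x$window[["m"]], ",", x$window[["n"]], ") —",
      x$n_positives, "positives /", x$n_negatives, "negatives\n\n")
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Extract trained position weights
#'
#' @param object A fitted \code{"lipid_model"}.
#' @param ... Unused.
#' @return Named list of numeric weight vectors, one per group.
#' @export
coef.lipid_model <- function(object, ...) {
  w <- lapply(object$groups, `[[`, "weights")
  names(w) <- vapply(object$groups, `[[`, character(1), "group_id")
  w
}

#' Plot the leave-one-out ROC curve of a fitted model
#'
#' @param x A fitted \code{"lipid_model"}.
#' @param ts The training set the model was fitted on.
#' @param ... Passed to \code{plot}.
#' @export
plot.lipid_model <- function(x, ts, ...) {
  sl <- loo_scores(x, ts)
  r <- roc_auc(sl$score, sl$label)
  plot(r$curve$fpr, r$curve$tpr, type = "l", xlab = "1 - Sp", ylab = "Sn",
       main = sprintf("%s LOO ROC (AUC = %.3f)", x$mod_type, r$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(r)
}
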