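## Cross-validation and performance metrics.
##
## The model is evaluated with leave-one-out and stratified k-fold
## cross-validation.  A site's score is the maximum of its scores over the
## model's groups; for LOO a positive is scored against its own group with
## itself removed, so no retraining is needed per held-out site.

#' Thresholded classification metrics
#'
#' Sensitivity, specificity, accuracy, Matthews correlation coefficient
#' and precision from confusion counts.  Precision is 0 when nothing is
#' called positive; the MCC is 0 when its denominator vanishes.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts; both classes must be
#'   represented (tp + fn > 0 and tn + fp > 0).
#' @return Named list with \code{sn}, \code{sp}, \code{ac}, \code{mcc},
#'   \code{pr}.
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fn == 0 || tn + fp == 0) {
    stop("both classes must be represented")
  }
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(sn = tp / (tp + fn),
       sp = tn / (tn + fp),
       ac = (tp + tn) / (tp + fp + tn + fn),
       mcc = if (denom == 0) 0 else (tp * tn - fp * fn) / denom,
       pr = if (tp + fp == 0) 0 else tp / (tp + fp))
}

#' Leave-one-out scores of a fitted model on its training set
#'
#' Each positive is scored with itself excluded from its own group's
#' peptides (other groups in full); each negative is scored against all
#' full groups.  The reported score is the maximum over groups.  A
#' positive whose exclusion empties its group is scored by the remaining
#' groups only (sentinel \code{-Inf} if none).
#'
#' @param model A fitted \code{"lipid_model"}.
#' @param ts The training set the model was fitted on (same window data).
#' @return Data.frame with columns \code{score}, \code{label}
#'   (\code{"pos"}/\code{"neg"}), \code{protein_id}, \code{position}.
#' @export
loo_scores <- function(model, ts) {
  m <- model$window[["m"]]; n <- model$window[["n"]]
  labels <- group_labels_from_model(model, ts)
  weights <- lapply(model$groups, `[[`, "weights")
  deltas <- lapply(model$groups, `[[`, "matrix_deltas")
  sl <- pooled_loo(ts, labels, m, n, weights = weights, deltas = deltas)
  sl$protein_id <- c(ts$positives$protein_id, ts$negatives$protein_id)
  sl$position <- c(ts$positives$position, ts$negatives$position)
  sl
}

## Recover each positive's group index from the model's stored site keys.
group_labels_from_model <- function(model, ts) {
  keys <- paste(ts$positives$protein_id, ts$positives$position, sep = ":")
  labels <- rep(NA_integer_, length(keys))
  for (g in seq_along(model$groups)) {
    labels[keys %in% model$groups[[g]]$site_keys] <- g
  }
  if (anyNA(labels)) {
    stop("training set does not match the model's stored sites")
  }
  labels
}

#' Stratified k-fold cross-validation scores
#'
#' Positives and negatives are split into k folds of near-equal size
#' (seeded shuffle).  In the default fast mode the trained weights and
#' matrix deltas are kept and each fold's held-out sites are scored
#' against groups rebuilt from the remaining folds' positives; with
#' \code{refit = "full"} weight training and matrix mutation are re-run on
#' each training split.
#'
#' @param model A fitted \code{"lipid_model"}.
#' @param ts Its training set.
#' @param k Number of folds (4, 6, 8 or 10; any k <= positives works).
#' @param seed Seed for the fold shuffle.
#' @param refit \code{"fast"} or \code{"full"}.
#' @param control Training control used when \code{refit = "full"}.
#' @return Data.frame as in \code{\link{loo_scores}}, plus a \code{fold}
#'   column and a \code{refit} attribute recording the mode.
#' @export
kfold_scores <- function(model, ts, k, seed = 1L,
                         refit = c("fast", "full"),
                         control = model$control) {
  refit <- match.arg(refit)
  npos <- nrow(ts$positives)
  nneg <- nrow(ts$negatives)
  if (k > npos) stop("k exceeds the number of positives")
  folds_pos <- make_folds(npos, k, derive_seed(seed, 1L))
  folds_neg <- make_folds(nneg, k, derive_seed(seed, 2L))
  labels <- group_labels_from_model(model, ts)
  m <- model$window[["m"]]; n <- model$window[["n"]]
  pos_pep <- trim_windows(ts$positives$peptide, m, n)
  neg_pep <- trim_windows(ts$negatives$peptide, m, n)

  out <- vector("list", k)
  for (f in seq_len(k)) {
    hold_pos <- which(folds_pos == f)
    hold_neg <- which(folds_neg == f)
    train_pos <- which(folds_pos != f)
    groups <- list()
    for (g in seq_along(model$groups)) {
      members <- intersect(which(labels == g), train_pos)
      if (length(members) == 0L) next
      grp <- model$groups[[g]]
      grp$peptides <- pos_pep[members]
      if (refit == "full" && control$max_iter > 0L) {
        grp$weights <- rep(1, m + n + 1L)
        grp$matrix_deltas <- rep(0, 210)
        grp <- train_weights(grp, neg_pep[folds_neg != f], control,
                             seed = derive_seed(seed, 300L + f * 10L + g))
        grp <- mutate_matrix(grp, neg_pep[folds_neg != f], control,
                             seed = derive_seed(seed, 600L + f * 10L + g))
      }
      groups[[length(groups) + 1L]] <- grp
    }
    sub <- model
    sub$groups <- groups
    pep <- c(pos_pep[hold_pos], neg_pep[hold_neg])
    scores <- model_group_scores(sub, pep)
    scores <- matrix(scores, nrow = length(pep))
    out[[f]] <- data.frame(
      score = apply(scores, 1, max),
      label = rep(c("pos", "neg"), c(length(hold_pos), length(hold_neg))),
      protein_id = c(ts$positives$protein_id[hold_pos],
                     ts$negatives$protein_id[hold_neg]),
      position = c(ts$positives$position[hold_pos],
                   ts$negatives$position[hold_neg]),
      fold = f, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "refit") <- refit
  res
}

## Balanced fold assignment: sizes differ by at most one, seeded shuffle.
make_folds <- function(n, k, seed) {
  idx <- rep_len(seq_len(k), n)
  with_seed(seed, idx[sample.int(n)])
}

#' ROC curve and area under it
#'
#' The curve is swept over all distinct score thresholds (a site is called
#' positive when score >= threshold).  The AUC equals the normalized
#' Mann-Whitney statistic, with ties between a positive and a negative
#' score counting one half.
#'
#' @param score Numeric scores.
#' @param label \code{"pos"}/\code{"neg"} labels (or a logical vector,
#'   TRUE = positive).
#' @return List with \code{curve} (data.frame threshold, fpr, tpr) and
#'   \code{auc}.
#' @export
roc_auc <- function(score, label) {
  lab <- normalize_labels(label)
  np <- sum(lab); nn <- sum(!lab)
  if (np == 0L || nn == 0L) stop("need at least one positive and one negative")
  ## Mann-Whitney via midranks (ties count 1/2)
  r <- rank(score)
  auc <- (sum(r[lab]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(score[lab] >= t), numeric(1)) / np
  fpr <- vapply(thr, function(t) sum(score[!lab] >= t), numeric(1)) / nn
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  list(curve = curve, auc = auc)
}

#' Precision-recall curve
#'
#' Precision and recall at every distinct score threshold, swept from the
#' highest score down (recall is monotone non-decreasing along the sweep).
#'
#' @inheritParams roc_auc
#' @return Data.frame with columns threshold, recall, precision.
#' @export
pr_curve <- function(score, label) {
  lab <- normalize_labels(label)
  np <- sum(lab); nn <- sum(!lab)
  if (np == 0L || nn == 0L) stop("need at least one positive and one negative")
  thr <- sort(unique(score), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(score[lab] >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(score[!lab] >= t), numeric(1))
  data.frame(threshold = thr, recall = tp / np,
             precision = ifelse(tp + fp == 0, 0, tp / (tp + fp)))
}

normalize_labels <- function(label) {
  if (is.logical(label)) return(label)
  if (!all(label %in% c("pos", "neg"))) {
    stop("labels must be 'pos'/'neg' or logical")
  }
  label == "pos"
}

#' Calibrate stringency cutoffs from scored negatives
#'
#' The cutoff of each stringency level is the minimal observed score at
#' which the specificity on the negatives reaches the level (0.95 / 0.90 /
#' 0.85 for high / medium / low by default).  An unreachable level places
#' the cutoff just above the maximum negative score, with a warning.
#'
#' @param neg_scores Numeric scores of negative sites.
#' @param sp_levels Named specificity levels, decreasing from high to low.
#' @return Named numeric vector of cutoffs, ordered high >= medium >= low.
#' @export
calibrate_thresholds <- function(neg_scores,
                                 sp_levels = c(high = 0.95, medium = 0.90,
                                               low = 0.85)) {
  if (length(neg_scores) == 0L) stop("no negative scores to calibrate on")
  cuts <- vapply(sp_levels, function(sp) {
    cut <- cutoff_at_sp(neg_scores, sp)
    if (cut > max(neg_scores)) {
      warning(sprintf("specificity %.2f unreachable; cutoff above max score", sp))
    }
    cut
  }, numeric(1))
  cuts
}

#' Thresholded evaluation report
#'
#' Confusion metrics of scored labels at a set of cutoffs (all distinct
#' scores by default).
#'
#' @inheritParams roc_auc
#' @param thresholds Cutoffs to evaluate (default: distinct scores).
#' @return Data.frame with threshold, sn, sp, ac, mcc, pr.
#' @export
evaluation_report <- function(score, label, thresholds = NULL) {
  lab <- normalize_labels(label)
  if (is.null(thresholds)) thresholds <- sort(unique(score), decreasing = TRUE)
  rows <- lapply(thresholds, function(t) {
    tp <- sum(score[lab] >= t); fn <- sum(lab) - tp
    fp <- sum(score[!lab] >= t); tn <- sum(!lab) - fp
    c(threshold = t, unlist(classification_metrics(tp, fp, tn, fn)))
  })
  as.data.frame(do.call(rbind, rows))
}
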