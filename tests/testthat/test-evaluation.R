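test_that("confusion metrics follow their standard definitions", {
  m <- classification_metrics(tp = 5, fp = 0, tn = 5, fn = 0)
  expect_equal(unlist(m), c(sn = 1, sp = 1, ac = 1, mcc = 1, pr = 1))

  m <- classification_metrics(tp = 8, fp = 10, tn = 90, fn = 2)
  expect_equal(m$sn, 0.8)
  expect_equal(m$sp, 0.9)
  expect_equal(m$ac, 98 / 110)

  # degenerate guards
  m <- classification_metrics(tp = 0, fp = 0, tn = 10, fn = 5)
  expect_equal(m$pr, 0)
  expect_equal(m$mcc, 0)
  expect_error(classification_metrics(0, 0, 0, 0), "both classes")
})

test_that("accuracy decomposes into class-weighted Sn and Sp", {
  withr_seed(3, {
    for (i in 1:20) {
      tp <- sample(0:30, 1); fn <- sample(1:30, 1)
      fp <- sample(0:30, 1); tn <- sample(1:30, 1)
      m <- classification_metrics(tp, fp, tn, fn)
      P <- tp + fn; N <- tn + fp
      expect_equal(m$ac, (m$sn * P + m$sp * N) / (P + N))
    }
  })
})

test_that("ROC AUC equals the pairwise Mann-Whitney count", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1),
                       c("pos", "pos", "neg", "neg"))$auc, 1)
  expect_equal(roc_auc(rep(1, 10), rep(c("pos", "neg"), 5))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1),
                       c("pos", "pos", "neg", "neg"))$auc, 0.75)

  withr_seed(11, {
    for (i in 1:30) {
      n <- sample(5:60, 1)
      score <- round(rnorm(n), 1)  # coarse scores force ties
      label <- ifelse(runif(n) < 0.4, "pos", "neg")
      if (length(unique(label)) < 2) next
      expect_equal(roc_auc(score, label)$auc, brute_force_auc(score, label))
    }
  })
  expect_error(roc_auc(1:3, rep("pos", 3)), "at least one")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr_seed(13, {
    score <- rnorm(50)
    label <- ifelse(runif(50) < 0.5, "pos", "neg")
    a0 <- roc_auc(score, label)$auc
    expect_equal(roc_auc(exp(score), label)$auc, a0)
    expect_equal(roc_auc(5 * score - 2, label)$auc, a0)
    expect_equal(roc_auc(atan(score), label)$auc, a0)
  })
})

test_that("the ROC curve integrates to the rank AUC", {
  withr_seed(17, {
    score <- round(rnorm(80), 1)
    label <- ifelse(runif(80) < 0.5, "pos", "neg")
    r <- roc_auc(score, label)
    # trapezoid over the full sweep (appending the (1,1) endpoint)
    fpr <- c(r$curve$fpr, 1); tpr <- c(r$curve$tpr, 1)
    trap <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
    expect_equal(trap, r$auc)
  })
})

test_that("precision-recall curves match exhaustive threshold enumeration", {
  score <- c(0.9, 0.5, 0.3)
  label <- c("pos", "neg", "pos")
  pr <- pr_curve(score, label)
  expect_equal(pr$recall, c(0.5, 0.5, 1.0))
  expect_equal(pr$precision, c(1, 0.5, 2 / 3))
  expect_true(all(diff(pr$recall) >= 0))

  # perfect separation: precision 1 at recall 1
  pr2 <- pr_curve(c(0.9, 0.8, 0.2, 0.1), c("pos", "pos", "neg", "neg"))
  expect_equal(pr2$precision[pr2$recall == 1][1], 1)

  # all-tied scores: precision equals prevalence at recall 1
  pr3 <- pr_curve(rep(1, 10), rep(c("pos", "neg"), c(3, 7)))
  expect_equal(pr3$recall, 1)
  expect_equal(pr3$precision, 0.3)
})

test_that("stringency cutoffs are minimal scores at the target specificity", {
  cuts <- calibrate_thresholds(as.numeric(1:100))
  expect_equal(unname(cuts["medium"]), 91)   # 10 of 100 negatives at/above
  expect_equal(unname(cuts["high"]), 96)
  expect_equal(unname(cuts["low"]), 86)
  expect_true(cuts["high"] >= cuts["medium"] &&
              cuts["medium"] >= cuts["low"])

  expect_warning(c2 <- calibrate_thresholds(rep(5, 10),
                                            sp_levels = c(top = 1.0)),
                 "unreachable")
  expect_gt(c2[["top"]], 5)
})

test_that("LOO scores drop the held-out positive from its own group", {
  # two identical positives: each LOO score equals the score vs the other
  p <- c(a = paste0("MG", strrep("A", 20), "G"),
         b = paste0("MG", strrep("A", 20), "G"))
  s <- data.frame(protein_id = c("a", "b"), position = 2L, residue = "G",
                  mod_type = "MYR", evidence = "experimental",
                  stringsAsFactors = FALSE)
  ctl <- train_control(seed = 1, max_iter = 0, mls_grid = cbind(2, 2),
                       min_group = 1)
  m <- lipid_train(p, s, "MYR", ctl)
  ts <- build_training_set(p, s, "MYR")
  sl <- loo_scores(m, ts)
  pos <- sl[sl$label == "pos", ]
  other <- peptide_score("*MGAA", m$groups[[1]])
  expect_equal(pos$score, rep(other, 2))
  expect_gt(pos$score[1], 0)

  # LOO never exceeds resubstitution for a self-similar peptide
  fix <- cached_tiny_model()
  sl2 <- loo_scores(fix$model, fix$ts)
  resub <- lipidsite:::model_group_scores(
    fix$model, lipidsite:::trim_windows(fix$ts$positives$peptide,
                                        fix$model$window[["m"]],
                                        fix$model$window[["n"]]))
  resub <- apply(matrix(resub, nrow = nrow(fix$ts$positives)), 1, max)
  expect_true(all(sl2$score[sl2$label == "pos"] <= resub + 1e-9))
})

test_that("k-fold splits are stratified, balanced and seeded", {
  fix <- cached_tiny_model()
  kf1 <- kfold_scores(fix$model, fix$ts, k = 5, seed = 4)
  kf2 <- kfold_scores(fix$model, fix$ts, k = 5, seed = 4)
  expect_identical(kf1, kf2)
  kf3 <- kfold_scores(fix$model, fix$ts, k = 5, seed = 5)
  expect_false(identical(kf1$score, kf3$score))

  sizes <- table(kf1$fold, kf1$label)
  expect_lte(diff(range(sizes[, "pos"])), 1)
  expect_lte(diff(range(sizes[, "neg"])), 1)
  expect_error(kfold_scores(fix$model, fix$ts, k = 1000), "exceeds")

  # every site scored exactly once
  expect_identical(nrow(kf1), nrow(fix$ts$positives) + nrow(fix$ts$negatives))
})
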