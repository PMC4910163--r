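test_that("training sets pair annotated positives with candidate negatives", {
  p <- c(p1 = "MGCGC")
  s <- data.frame(protein_id = "p1", position = 2L, residue = "G",
                  mod_type = "MYR", evidence = "experimental",
                  stringsAsFactors = FALSE)
  ts <- build_training_set(p, s, "MYR")
  expect_identical(ts$positives$position, 2L)
  expect_identical(ts$negatives$position, 4L)

  s2 <- data.frame(protein_id = "p1", position = 3L, residue = "C",
                   mod_type = "PALM", evidence = "experimental",
                   stringsAsFactors = FALSE)
  ts2 <- build_training_set(p, s2, "PALM")
  expect_identical(ts2$negatives$position, 5L)

  expect_error(build_training_set(p, s, "FARN"), "no positive sites")

  # stored windows are the full 61-mers
  expect_identical(unique(nchar(ts$positives$peptide)), 61L)
})

test_that("motif length selection prefers informative, then shorter windows", {
  fix <- cached_tiny_model()
  ts <- fix$ts
  labels <- rep(1L, nrow(ts$positives))
  expect_identical(select_motif_length(ts, labels, cbind(7, 7)), c(7L, 7L))
  expect_error(select_motif_length(ts, labels, cbind(31, 7)), "exceeds")

  # the planted myristoylation signal spans positions +1..+5: a (1,5)
  # window must beat (1,1) wherever they differ, and ties go short
  sn <- function(mn) {
    sl <- lipidsite:::pooled_loo(ts, labels, mn[1], mn[2])
    lipidsite:::sn_at_sp(sl$score[sl$label == "pos"],
                         sl$score[sl$label == "neg"], 0.9)
  }
  pick <- select_motif_length(ts, labels, rbind(c(1, 1), c(1, 5)))
  if (sn(c(1, 5)) > sn(c(1, 1))) {
    expect_identical(pick, c(1L, 5L))
  } else {
    expect_identical(pick, c(1L, 1L))
  }
})

test_that("a zero-iteration budget leaves weights and matrix unchanged", {
  fix <- cached_tiny_model()
  grp <- fix$model$groups[[1]]
  neg <- lipidsite:::trim_windows(fix$ts$negatives$peptide,
                                  fix$model$window[["m"]],
                                  fix$model$window[["n"]])
  ctl0 <- train_control(seed = 1, max_iter = 0)
  g <- train_weights(grp, neg, ctl0)
  expect_equal(g$weights, rep(1, nchar(grp$peptides[[1]])))
  g <- mutate_matrix(grp, neg, ctl0)
  expect_equal(g$matrix_deltas, rep(0, 210))
})

test_that("weight training and matrix mutation never degrade the objective", {
  fix <- cached_tiny_model()
  for (g in fix$model$groups) {
    tr <- g$objective_trace
    expect_gte(tr[["after_wt"]], tr[["baseline"]])
    expect_gte(tr[["after_mam"]], tr[["after_wt"]])
  }
  # matrix deltas stay inside the configured box
  for (g in fix$model$groups) {
    expect_true(all(abs(g$matrix_deltas) <= 4 + 1e-12))
    expect_true(all(g$weights >= 0))
  }
})

test_that("trained weights concentrate on planted signal positions", {
  # weak signal only at positions -1..+1 of the center; noise elsewhere
  set.seed(5)
  motif <- c("K", "C", "S")
  pos_pep <- replicate(30, {
    bg <- sample(aa_alphabet()[1:20], 9, replace = TRUE)
    hit <- runif(3) < 0.6
    bg[4:6][hit] <- motif[hit]
    bg[5] <- "C"
    paste(bg, collapse = "")
  })
  neg_pep <- replicate(150, {
    bg <- sample(aa_alphabet()[1:20], 9, replace = TRUE)
    bg[5] <- "C"
    paste(bg, collapse = "")
  })
  grp <- list(group_id = "g", kind = "test", peptides = pos_pep,
              weights = rep(1, 9), matrix_deltas = rep(0, 210))
  ctl <- train_control(seed = 2, max_iter = 80)
  g <- train_weights(grp, neg_pep, ctl)
  signal <- g$weights[c(4, 6)]     # the trained flanks
  noise <- g$weights[c(1:3, 7:9)]
  expect_gt(mean(signal), mean(noise))
})

test_that("the full fit is deterministic and self-consistent", {
  fix <- cached_tiny_model()
  d <- fix$data
  m1 <- suppressWarnings(lipid_train(d$proteins, d$sites, "MYR", fix$control))
  f1 <- tempfile(); f2 <- tempfile()
  write_model(m1, f1)
  write_model(fix$model, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))

  # a training positive is recovered at low stringency
  hits <- predict(fix$model, d$proteins, "low")
  keys <- paste(hits$protein_id, hits$position)
  truth <- paste(d$sites$protein_id, d$sites$position)
  expect_gt(mean(truth %in% keys), 0.5)
})

test_that("raising stringency never adds predicted sites", {
  fix <- cached_tiny_model()
  d <- fix$data
  key <- function(h) paste(h$protein_id, h$position)
  hi <- key(predict(fix$model, d$proteins, "high"))
  me <- key(predict(fix$model, d$proteins, "medium"))
  lo <- key(predict(fix$model, d$proteins, "low"))
  expect_true(all(hi %in% me))
  expect_true(all(me %in% lo))
})

test_that("proteins without candidate residues yield no predictions", {
  fix <- cached_tiny_model()
  out <- predict(fix$model, c(ala = "AAAAAAAA"), "low")
  expect_identical(nrow(out), 0L)
})

test_that("models round-trip bit-exactly through JSON", {
  fix <- cached_tiny_model()
  f1 <- tempfile(); f2 <- tempfile()
  write_model(fix$model, f1)
  m2 <- read_model(f1)
  write_model(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and the round-tripped model predicts identically
  p1 <- predict(fix$model, fix$data$proteins, "medium")
  p2 <- predict(m2, fix$data$proteins, "medium")
  expect_equal(p1, p2)
  unlink(c(f1, f2))
})

test_that("undersized groups are merged with a warning", {
  # 5 consensus positives and a single nonconsensus one
  seqs <- character(6)
  sites <- NULL
  set.seed(8)
  for (i in 1:5) {
    bg <- paste(sample(aa_alphabet()[1:20], 40, replace = TRUE), collapse = "")
    seqs[i] <- paste0("MGQLFS", bg)
    sites <- rbind(sites, data.frame(protein_id = paste0("c", i), position = 2L,
                                     residue = "G", mod_type = "MYR",
                                     evidence = "experimental"))
  }
  seqs[6] <- paste0("MAAGAA", paste(sample(aa_alphabet()[1:20], 40,
                                           replace = TRUE), collapse = ""))
  sites <- rbind(sites, data.frame(protein_id = "c6", position = 4L,
                                   residue = "G", mod_type = "MYR",
                                   evidence = "experimental"))
  names(seqs) <- c(paste0("c", 1:5), "c6")
  ctl <- train_control(seed = 1, max_iter = 0, mls_grid = cbind(2, 2))
  expect_warning(m <- lipid_train(seqs, sites, "MYR", ctl), "merged")
  expect_length(m$groups, 1)
  expect_length(m$groups[[1]]$peptides, 6)
})
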