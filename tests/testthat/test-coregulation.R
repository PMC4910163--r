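test_that("the significance transform is -ln(p)", {
  expect_lt(abs(significance(0.05) - 2.99), 0.01)
  expect_lt(abs(significance(0.01) - 4.61), 0.01)
  expect_equal(significance(1), 0)
  s0 <- significance(0)
  expect_true(attr(s0, "capped"))
  expect_equal(as.numeric(s0), -log(.Machine$double.xmin))
})

test_that("co-occurrence chi-square matches the closed form", {
  mklib <- function(tab) {
    # build a library of proteins realizing the 2x2 co-occurrence table
    n <- sum(tab)
    proteins <- setNames(rep("MGCCGC", n), sprintf("q%03d", 1:n))
    rows <- list()
    i <- 0
    add <- function(id, myr, palm) {
      out <- NULL
      if (myr) out <- rbind(out, data.frame(protein_id = id, position = 2L,
                                            residue = "G", mod_type = "MYR",
                                            evidence = "experimental"))
      if (palm) out <- rbind(out, data.frame(protein_id = id, position = 3L,
                                             residue = "C", mod_type = "PALM",
                                             evidence = "experimental"))
      out
    }
    cell <- as.vector(t(tab))
    flags <- cbind(rep(c(TRUE, TRUE, FALSE, FALSE), cell),
                   rep(c(TRUE, FALSE, TRUE, FALSE), cell))
    sites <- do.call(rbind, lapply(seq_len(n), function(i) {
      add(names(proteins)[i], flags[i, 1], flags[i, 2])
    }))
    structure(list(proteins = proteins, sites = sites),
              class = "lipid_library")
  }

  r <- cooccurrence_test(mklib(matrix(c(10, 10, 10, 10), 2)), "MYR", "PALM")
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  r <- cooccurrence_test(mklib(matrix(c(30, 10, 10, 30), 2, byrow = TRUE)),
                         "MYR", "PALM")
  expect_equal(r$statistic, 20)

  # symmetry in the pair
  lib <- mklib(matrix(c(17, 5, 8, 21), 2, byrow = TRUE))
  r1 <- cooccurrence_test(lib, "MYR", "PALM")
  r2 <- cooccurrence_test(lib, "PALM", "MYR")
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p, r2$p)

  # zero margin is degenerate, not an error
  libd <- mklib(matrix(c(0, 0, 10, 10), 2, byrow = TRUE))
  rd <- cooccurrence_test(libd, "MYR", "PALM")
  expect_true(rd$degenerate)
  expect_equal(rd$p, 1)
})

test_that("2x2 chi-square equals the closed form on random tables", {
  withr_seed(21, {
    for (i in 1:100) {
      tab <- matrix(sample(1:40, 4, replace = TRUE), 2)
      got <- lipidsite:::chisq_2x2(tab)
      want <- closed_form_chisq(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
      expect_equal(got$statistic, want)
      expect_equal(got$p, pchisq(want, df = 1, lower.tail = FALSE))
    }
  })
})

test_that("proximity counts realize the constructed fixture exactly", {
  # protein design: every MYR glycine has a PALM cysteine next door,
  # no unmodified glycine does
  proteins <- c(x1 = "AAGCAAAAAAAAGAAAAAAA",
                x2 = "AAGCAAAAAAAAGAAAAAAA")
  sites <- rbind(
    data.frame(protein_id = c("x1", "x2"), position = 3L, residue = "G",
               mod_type = "MYR", evidence = "experimental"),
    data.frame(protein_id = c("x1", "x2"), position = 4L, residue = "C",
               mod_type = "PALM", evidence = "experimental"))
  lib <- structure(list(proteins = proteins, sites = sites),
                   class = "lipid_library")
  r <- proximity_test(lib, "MYR", "PALM", window = c(5, 5))
  expect_equal(unname(r$table), matrix(c(2, 0, 0, 2), 2, byrow = TRUE))
  expect_equal(r$statistic, closed_form_chisq(2, 0, 0, 2))

  # widening the window can only add "near" counts
  r15 <- proximity_test(lib, "MYR", "PALM", window = c(15, 15))
  expect_gte(r15$table[1, 1], r$table[1, 1])
  expect_gte(r15$table[2, 1], r$table[2, 1])

  expect_error(proximity_test(lib, "MYR", "MYR"), "different types")
  expect_error(proximity_test(structure(list(proteins = proteins,
                                             sites = sites[3:4, ]),
                                        class = "lipid_library"),
                              "MYR", "PALM"), "no MYR sites")
})

test_that("in-situ hypergeometric test matches exhaustive enumeration", {
  mkcyslib <- function(N, K, n, k) {
    # one protein with N cysteines; K carry PALM, n carry FARN, k overlap
    proteins <- c(z = paste(rep("C", N), collapse = ""))
    palm <- seq_len(K)
    farn <- c(seq_len(k), if (n > k) (K + 1):(K + n - k))
    sites <- rbind(
      if (K > 0) data.frame(protein_id = "z", position = palm, residue = "C",
                            mod_type = "PALM", evidence = "experimental"),
      if (n > 0) data.frame(protein_id = "z", position = farn, residue = "C",
                            mod_type = "FARN", evidence = "experimental"))
    structure(list(proteins = proteins, sites = sites),
              class = "lipid_library")
  }

  r <- insitu_test(mkcyslib(10, 5, 5, 5), "FARN", "PALM")
  expect_equal(r$p, 1 / choose(10, 5))
  expect_equal(r$enrichment_ratio, 2)

  r0 <- insitu_test(mkcyslib(12, 4, 5, 0), "FARN", "PALM")
  expect_equal(r0$p, 1)

  # enrichment 1 when k/n equals K/N
  r1 <- insitu_test(mkcyslib(12, 6, 4, 2), "FARN", "PALM")
  expect_equal(r1$enrichment_ratio, 1)

  withr_seed(31, {
    for (i in 1:60) {
      N <- sample(4:30, 1)
      K <- sample(1:N, 1)
      n <- sample(1:N, 1)
      k <- sample(max(0, n + K - N):min(n, K), 1)
      lib <- mkcyslib(N, K, n, k)
      r <- insitu_test(lib, "FARN", "PALM")
      expect_equal(r$p, brute_force_hyper_tail(k, N, K, n))
    }
  })
})

test_that("null libraries calibrate the co-occurrence p-values", {
  ps <- vapply(1:150, function(s) {
    lib <- synth_null_library(n_proteins = 40, seed = 1000 + s)
    cooccurrence_test(lib, "PALM", "MYR")$p
  }, numeric(1))
  # roughly uniform: KS test should not reject at the 1% level
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
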