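test_that("the embedded base matrix reproduces published BLOSUM62", {
  ref <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  aa <- c(aa_alphabet()[1:20], "X")
  expect_true(all(blosum62()[aa, aa] == ref[aa, aa]))
  expect_true(isSymmetric(blosum62()))
  expect_true(all(blosum62()["*", ] == 0))
  expect_true(all(blosum62()[, "*"] == 0))
  expect_true(all(diag(blosum62())[1:20] > 0))
})

test_that("conserved substitutions are positive-scoring pairs", {
  expect_true(is_conserved("C", "C"))
  expect_true(is_conserved("L", "I"))
  expect_false(is_conserved("W", "G"))
  expect_false(is_conserved("A", "*"))
  expect_error(is_conserved("B", "A"), "unknown residue")
})

test_that("peptide similarity follows the conserved-fraction definition", {
  expect_equal(peptide_similarity("CAC", "CAC"), list(s = 1, d = 1))
  s <- peptide_similarity("AAA", "WWW")
  expect_equal(s$s, 0)
  expect_identical(s$d, Inf)
  expect_equal(peptide_similarity("CAC", "CWC")$s, 2 / 3)
  expect_error(peptide_similarity("CAC", "CACA"), "length")
})

test_that("similarity is symmetric and degrades with corruption", {
  peps <- random_peptides(12, 9, seed = 42)
  for (i in 1:6) {
    a <- peps[2 * i - 1]; b <- peps[2 * i]
    expect_equal(peptide_similarity(a, b)$s, peptide_similarity(b, a)$s)
  }
  # corrupting residues to a non-conserved partner never raises s
  a <- "CKLSMAEQT"
  b <- a
  s_prev <- peptide_similarity(a, b)$s
  for (pos in c(2, 5, 8)) {
    substr(b, pos, pos) <- "W"  # W is non-conserved vs K, M, Q
    s_new <- peptide_similarity(a, b)$s
    expect_lte(s_new, s_prev)
    s_prev <- s_new
  }
})

test_that("group scoring is a weighted mean over training peptides", {
  g <- list(peptides = "CCC", weights = c(1, 1, 1), matrix_deltas = NULL)
  expect_equal(peptide_score("CCC", g), 3 * blosum62()["C", "C"])

  g$weights <- c(0, 0, 0)
  expect_equal(peptide_score("CKL", g), 0)

  # linear in the weights
  g1 <- list(peptides = c("CKLSM", "CALTM", "CRLNM"),
             weights = c(1, 0.5, 2, 1, 0.2), matrix_deltas = NULL)
  g2 <- g1; g2$weights <- 2 * g1$weights
  q <- "CQLAM"
  expect_equal(peptide_score(q, g2), 2 * peptide_score(q, g1))

  # invariant to the order of the training peptides
  g3 <- g1; g3$peptides <- rev(g1$peptides)
  expect_equal(peptide_score(q, g3), peptide_score(q, g1))

  # mean semantics: duplicating every member leaves the score unchanged
  g4 <- g1; g4$peptides <- rep(g1$peptides, 2)
  expect_equal(peptide_score(q, g4), peptide_score(q, g1))

  expect_error(peptide_score("CCC", list(peptides = character(0),
                                         weights = 1)), "empty group")
})

test_that("padding is neutral in scores", {
  g <- list(peptides = "*AC", weights = c(1, 1, 1), matrix_deltas = NULL)
  expect_equal(peptide_score("*AC", g),
               blosum62()["A", "A"] + blosum62()["C", "C"])
  expect_equal(peptide_score("WAC", g),
               blosum62()["A", "A"] + blosum62()["C", "C"])
})

test_that("matrix deltas stay symmetric and bounded to the tuned pairs", {
  deltas <- rep(0, 210)
  names_ <- matrix_pair_names()
  deltas[match("A:R", names_)] <- 1.5
  deltas[match("C:C", names_)] <- -2
  m <- substitution_matrix(deltas)
  expect_equal(m["A", "R"], blosum62()["A", "R"] + 1.5)
  expect_equal(m["R", "A"], m["A", "R"])
  expect_equal(m["C", "C"], blosum62()["C", "C"] - 2)
  expect_true(isSymmetric(m))
  # untouched rows
  expect_equal(m["X", ], blosum62()["X", ])
  expect_equal(m["*", ], blosum62()["*", ])
})
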