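# Shared fixtures and independent oracles used across the test files.

# Random peptides over the standard alphabet.
random_peptides <- function(n, len, seed = 1) {
  withr_seed(seed, replicate(n, paste(sample(aa_alphabet()[1:20], len,
                                             replace = TRUE), collapse = "")))
}

withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Brute-force AUC: fraction of positive-negative pairs ranked correctly,
# ties counting one half.
brute_force_auc <- function(score, label) {
  pos <- score[label == "pos"]
  neg <- score[label == "neg"]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Closed-form Pearson chi-square for a 2x2 table.
closed_form_chisq <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Exhaustive upper-tail hypergeometric probability P(X >= k).
brute_force_hyper_tail <- function(k, N, K, n) {
  ks <- max(0, n - (N - K)):min(n, K)
  probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(probs[ks >= k])
}

# Rand index between two partitions.
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  }
  agree / choose(n, 2)
}

# Tiny two-protein dataset for seqio/training unit tests.
toy_proteins <- function() {
  c(p1 = "MGCIKSKRKDNLNDDGVDMKTQPVRNTERTIYVRDPTSC",
    p2 = "MGQLFSKCCGAKEARKCVIM")
}

toy_sites <- function() {
  data.frame(protein_id = c("p1", "p2", "p2"),
             position = c(2L, 2L, 8L),
             residue = c("G", "G", "C"),
             mod_type = c("MYR", "MYR", "PALM"),
             evidence = "experimental",
             stringsAsFactors = FALSE)
}

# Small trained model on a reduced budget, cached across test files.
cached_tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- synth_generate(synth_spec("MYR", n_pos = 25, seed = 7))
      ctl <- train_control(seed = 3, max_iter = 15,
                           mls_grid = cbind(m = c(1, 5), n = c(1, 5)))
      m <- suppressWarnings(lipid_train(d$proteins, d$sites, "MYR", ctl))
      ts <- build_training_set(d$proteins, d$sites, "MYR")
      cache <<- list(data = d, model = m, ts = ts, control = ctl)
    }
    cache
  }
})
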