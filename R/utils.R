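## Small internal utilities.

## Evaluate code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic sub-seed derivation, kept within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}

## MD5 checksum of the training inputs, for model provenance.
dataset_checksum <- function(proteins, sites) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "w")
  writeLines(paste(names(proteins), proteins, sep = "\t"), con)
  utils::write.table(sites, con, sep = "\t", row.names = FALSE)
  close(con)
  unname(tools::md5sum(tf))
}
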