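# Internal helpers: reproducible child seeds, sequence utilities, validation.

# Deterministic child seed from a parent seed and a stage label; keeps results
# of individual stages reproducible when re-run in isolation.
derive_seed <- function(seed, stage) {
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 31 + v) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# replace the substring of `seq` starting at 0-based `at` with `ins`
splice_in <- function(seq, at, ins) {
  substr(seq, at + 1, at + nchar(ins)) <- ins
  seq
}

stopifnot_prop <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single proportion in [0, 1]", name), call. = FALSE)
  }
}

stopifnot_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
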