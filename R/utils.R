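DNA_BASES <- c("A", "C", "G", "T")

# reverse-complement of uppercase DNA strings (vectorised)
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# first base of a read reported in RNA convention (T shown as U)
five_prime_base <- function(seq) {
  chartr("T", "U", substr(seq, 1L, 1L))
}

# deterministic 31-bit hash of a string; used to tie hotspot weights to a
# contig identity so the hotspot pattern repeats across libraries and seeds
hash31 <- function(x) {
  h <- 5381
  for (v in utf8ToInt(x)) h <- (h * 33 + v) %% 2147483647
  as.integer(h)
}

stopifnot_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", what),
         call. = FALSE)
  }
}

stopifnot_count <- function(x, what, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", what, min),
         call. = FALSE)
  }
}
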