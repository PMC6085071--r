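# Independent brute-force oracles and small fixture builders. These share no
# code with the package internals they check.

rc_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# sample a read from a contig with up to `n_sub` random substitutions
sample_read_from <- function(cseq, len, n_sub = 0) {
  lc <- nchar(cseq)
  s <- sample.int(lc - len + 1L, 1L)
  r <- substr(cseq, s, s + len - 1L)
  if (stats::runif(1) < 0.5) r <- rc_chr(r)
  if (n_sub > 0) {
    pos <- sample.int(len, n_sub)
    for (p in pos) {
      substr(r, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(r, p, p)), 1L)
    }
  }
  r
}

# exhaustive end-to-end Hamming scan over every offset and strand
oracle_map_e2e <- function(rseq, cseq, max_mm) {
  cv <- strsplit(cseq, "")[[1]]
  out <- list()
  for (strand in c("+", "-")) {
    rv <- strsplit(if (strand == "+") rseq else rc_chr(rseq), "")[[1]]
    L <- length(rv)
    noff <- length(cv) - L + 1L
    if (noff < 1L) next
    mm <- integer(noff)
    for (j in seq_len(L)) {
      mm <- mm + (cv[j:(j + noff - 1L)] != rv[j])
    }
    ok <- which(mm <= max_mm)
    if (length(ok)) {
      out[[strand]] <- data.frame(start = ok - 1L, strand = strand,
                                  mismatches = mm[ok])
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), strand = character(0),
                      mismatches = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$strand), , drop = FALSE]
}

# exhaustive ungapped local scan: every (read substring, diagonal) window of
# length >= min_core with <= max_mm mismatches, reduced to the single best
# placement by (core length desc, mismatches asc, start asc, + before -)
oracle_map_local <- function(rseq, cseq, max_mm, min_core = 15L) {
  cv <- utf8ToInt(cseq)
  lc <- length(cv)
  best <- NULL
  for (strand in c("+", "-")) {
    rv <- utf8ToInt(if (strand == "+") rseq else rc_chr(rseq))
    L <- length(rv)
    ds <- (-(L - min_core)):(lc - min_core)   # contig pos (0-based) of read pos 1
    nd <- length(ds)
    cpos <- outer(ds, 0:(L - 1L), "+")
    cpos[cpos < 0L | cpos >= lc] <- NA_integer_
    M <- matrix(cv[cpos + 1L], nd, L) !=
      matrix(rv, nd, L, byrow = TRUE)
    M <- 1 * M
    M[is.na(M)] <- 1e6   # out-of-contig positions poison any window
    CS <- cbind(0, M)
    for (j in 2:(L + 1L)) CS[, j] <- CS[, j] + CS[, j - 1L]
    for (len in L:min_core) {
      nw <- L - len + 1L
      W <- CS[, (1:nw) + len, drop = FALSE] - CS[, 1:nw, drop = FALSE]
      hit <- which(W <= max_mm, arr.ind = TRUE)
      if (nrow(hit)) {
        mm <- W[hit]
        starts <- ds[hit[, 1L]] + hit[, 2L] - 1L
        mm_min <- min(mm)
        start_min <- min(starts[mm == mm_min])
        cand <- list(len = len, mm = mm_min, start = start_min,
                     strand = strand)
        if (is.null(best) ||
            cand$len > best$len ||
            (cand$len == best$len &&
             (cand$mm < best$mm ||
              (cand$mm == best$mm && cand$start < best$start)))) {
          best <- cand
        }
        break
      }
    }
  }
  best
}

# dense grid-search prevalence MLE and 2-LL interval
oracle_prevalence_grid <- function(pool_sizes, positive, step = 1e-6) {
  p <- seq(0, 1, by = step)
  q <- 1 - p
  ll <- rep(0, length(p))
  for (i in seq_along(pool_sizes)) {
    pr <- 1 - q^pool_sizes[i]
    ll <- ll + if (positive[i]) ifelse(pr > 0, log(pr), -Inf) else
      ifelse(q > 0, pool_sizes[i] * log(q), -Inf)
  }
  imax <- which.max(ll)
  inside <- which(ll >= ll[imax] - 2)
  list(p_hat = p[imax], lower = p[min(inside)], upper = p[max(inside)])
}

# dense grid deviance oracle for the binomial strand-fraction LRT interval
oracle_binom_ci_grid <- function(pos, neg, conf = 0.95, step = 1e-6) {
  p <- seq(0, 1, by = step)
  ll <- (if (pos > 0) pos * log(p) else 0) +
    (if (neg > 0) neg * log(1 - p) else 0)
  phat <- pos / (pos + neg)
  llmax <- (if (pos > 0) pos * log(phat) else 0) +
    (if (neg > 0) neg * log(1 - phat) else 0)
  inside <- which(2 * (llmax - ll) <= stats::qchisq(conf, 1))
  c(lower = p[min(inside)], upper = p[max(inside)])
}

gini_coef <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (sum(x) == 0) return(0)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}

# direct construction of an alignment table (bypasses mapping) for statistics
# that only consume alignment coordinates
make_alignments <- function(start, end, strand, seq = NULL,
                            contig_id = "c1") {
  n <- length(start)
  if (is.null(seq)) {
    seq <- vapply(end - start, random_seq, character(1))
  }
  tibble::tibble(
    read_id = sprintf("r%04d", seq_len(n)),
    contig_id = contig_id,
    start = as.integer(start), end = as.integer(end),
    strand = strand,
    mismatches = 0L,
    read_length = as.integer(end - start),
    five_prime_base = chartr("T", "U", substr(seq, 1, 1)),
    seq = seq
  )
}
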