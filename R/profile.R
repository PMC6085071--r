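SIZE_RANGE <- 17:40
RNA_BASES <- c("A", "C", "G", "U")

#' Size x strand x 5'-base profile of alignments
#'
#' Pure counting of alignments over the complete grid of read length (17--40
#' nt), strand and 5' base, the numeric form of the classic small-RNA size
#' distribution coloured by 5' base.
#'
#' @param alignments Alignment tibble from [map_reads()].
#' @return A tibble with columns `length`, `strand`, `base`, `n` covering the
#'   full grid; `n` sums to the number of alignments.
#' @export
size_profile <- function(alignments) {
  grid <- tidyr::expand_grid(length = SIZE_RANGE, strand = c("+", "-"),
                             base = RNA_BASES)
  if (nrow(alignments) == 0L) return(dplyr::mutate(grid, n = 0L))
  counts <- alignments |>
    dplyr::count(length = .data$read_length, strand = .data$strand,
                 base = .data$five_prime_base)
  grid |>
    dplyr::left_join(counts, by = c("length", "strand", "base")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Modal read length per strand (ties broken toward the smaller length)
#'
#' @param profile A [size_profile()] tibble.
#' @return Tibble with `strand` and `modal_length` (`NA` for a strand with no
#'   alignments).
#' @export
modal_length <- function(profile) {
  profile |>
    dplyr::summarise(n = sum(.data$n), .by = c("strand", "length")) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$length) |>
    dplyr::summarise(
      modal_length = ifelse(sum(.data$n) == 0L, NA_integer_,
                            .data$length[1L]),
      .by = "strand")
}

#' 5'U fraction per strand
#'
#' @param profile A [size_profile()] tibble.
#' @return Tibble with `strand` and `five_prime_U_fraction` (`NA` when the
#'   strand has no alignments).
#' @export
five_prime_u_fraction <- function(profile) {
  profile |>
    dplyr::summarise(
      five_prime_U_fraction = ifelse(sum(.data$n) == 0L, NA_real_,
                                     sum(.data$n[.data$base == "U"]) /
                                       sum(.data$n)),
      .by = "strand")
}

#' Per-position 5'-end coverage along a contig
#'
#' Accumulates the 5' start positions of alignments per strand: the 5' end of
#' a `+` alignment is `start`, that of a `-` alignment is `end - 1`.
#'
#' @param alignments Alignment tibble (one contig).
#' @param contig_length Contig length in bp.
#' @return A tibble with `position` (0-based), `pos_starts`, `neg_starts`.
#' @export
positional_coverage <- function(alignments, contig_length) {
  if (nrow(alignments) > 0L &&
      (any(alignments$start < 0L) || any(alignments$end > contig_length))) {
    stop("alignment outside [0, contig_length)", call. = FALSE)
  }
  p5 <- ifelse(alignments$strand == "+", alignments$start,
               alignments$end - 1L)
  pos <- tabulate(p5[alignments$strand == "+"] + 1L, nbins = contig_length)
  neg <- tabulate(p5[alignments$strand == "-"] + 1L, nbins = contig_length)
  tibble::tibble(position = 0:(contig_length - 1L), pos_starts = pos,
                 neg_starts = neg)
}

#' Sequence logo of unique modal-length reads on one strand
#'
#' Deduplicates the sequences of the modal length on the requested strand and
#' computes, per position, base frequencies and information content
#' `IC = 2 + sum(f * log2(f))` bits (0 log 0 = 0; no small-sample
#' correction). Letter heights are `f * IC`, the standard logo scaling.
#'
#' @param alignments Alignment tibble with a `seq` column.
#' @param strand `"+"` or `"-"`.
#' @return A tibble with `position` (1-based within the read), `base`,
#'   `freq`, `ic`, `height`, plus attribute `n_unique`. Zero rows when the
#'   strand has no alignments.
#' @export
sequence_logo <- function(alignments, strand = c("+", "-")) {
  strand <- match.arg(strand)
  aln <- alignments[alignments$strand == strand, , drop = FALSE]
  empty <- tibble::tibble(position = integer(0), base = character(0),
                          freq = numeric(0), ic = numeric(0),
                          height = numeric(0))
  if (nrow(aln) == 0L) return(structure(empty, n_unique = 0L))
  ml <- modal_length(size_profile(aln))
  ml <- ml$modal_length[ml$strand == strand]
  if (is.na(ml)) return(structure(empty, n_unique = 0L))
  seqs <- unique(aln$seq[aln$read_length == ml])
  mat <- matrix(unlist(strsplit(chartr("T", "U", seqs), "", fixed = TRUE)),
                nrow = length(seqs), byrow = TRUE)
  out <- purrr::map_dfr(seq_len(ncol(mat)), function(j) {
    f <- vapply(RNA_BASES, function(b) mean(mat[, j] == b), numeric(1))
    ic <- 2 + sum(ifelse(f > 0, f * log2(f), 0))
    tibble::tibble(position = j, base = RNA_BASES, freq = unname(f),
                   ic = ic, height = unname(f) * ic)
  })
  structure(out, n_unique = length(seqs))
}

# 5'-end position of each alignment on the contig forward strand (0-based)
five_prime_positions <- function(alignments) {
  ifelse(alignments$strand == "+", alignments$start, alignments$end - 1L)
}

#' Ping-pong signature of a set of alignments
#'
#' For every opposite-strand alignment pair on the same contig, the 5'-to-5'
#' overlap is the span between the facing 5' ends, `o = e - s + 1`, where
#' `s` is the `+` read's 5' position and `e` the `-` read's; pairs are
#' counted when `1 <= o <= 30` (5' ends pointing away from each other never
#' count). Ping-pong amplification places the pair mode at exactly `o = 10`.
#'
#' `z10` scores the o = 10 count against the background counts at
#' `o` in 1--30 excluding 8--12 (the exclusion window keeps shoulder pairs
#' out of the null); it is `NA` when there are no pairs or the background is
#' degenerate. `pos10_A_fraction` is the fraction of unique read sequences
#' (length >= 10) per strand with an A at read position 10 -- the
#' complement-of-5'U mark expected on ping-pong secondaries.
#'
#' @param alignments Alignment tibble with `seq`.
#' @return An object of class `pingpong_result`: a list with
#'   `overlap_histogram` (tibble `overlap`, `n_pairs`), `z10`, `n_pairs`,
#'   and `pos10_A` (tibble `strand`, `pos10_A_fraction`, `n_unique`).
#' @export
ping_pong_signature <- function(alignments) {
  hist <- tibble::tibble(overlap = 1:30, n_pairs = 0)
  if (nrow(alignments) > 0L) {
    p5 <- five_prime_positions(alignments)
    pos <- tibble::tibble(contig_id = alignments$contig_id,
                          p5 = p5)[alignments$strand == "+", ]
    neg <- tibble::tibble(contig_id = alignments$contig_id,
                          p5 = p5)[alignments$strand == "-", ]
    if (nrow(pos) && nrow(neg)) {
      posg <- dplyr::count(pos, .data$contig_id, .data$p5, name = "n")
      negg <- dplyr::count(neg, .data$contig_id, .data$p5, name = "n")
      for (o in 1:30) {
        j <- dplyr::inner_join(
          posg, dplyr::mutate(negg, p5 = .data$p5 - o + 1L),
          by = c("contig_id", "p5"), suffix = c("_p", "_n"))
        hist$n_pairs[o] <- sum(j$n_p * j$n_n)
      }
    }
  }
  n_pairs <- sum(hist$n_pairs)
  bg <- hist$n_pairs[!hist$overlap %in% 8:12]
  z10 <- if (n_pairs > 0 && stats::sd(bg) > 0) {
    (hist$n_pairs[hist$overlap == 10] - mean(bg)) / stats::sd(bg)
  } else {
    NA_real_
  }
  pos10 <- purrr::map_dfr(c("+", "-"), function(s) {
    seqs <- unique(alignments$seq[alignments$strand == s &
                                    nchar(alignments$seq) >= 10L])
    tibble::tibble(
      strand = s,
      pos10_A_fraction = if (length(seqs)) {
        mean(substr(seqs, 10L, 10L) == "A")
      } else {
        NA_real_
      },
      n_unique = length(seqs))
  })
  structure(list(overlap_histogram = hist, z10 = z10, n_pairs = n_pairs,
                 pos10_A = pos10),
            class = "pingpong_result")
}

#' @export
print.pingpong_result <- function(x, ...) {
  cat("Ping-pong signature\n")
  cat("  pairs:", x$n_pairs, "\n")
  mode_o <- if (x$n_pairs > 0) {
    x$overlap_histogram$overlap[which.max(x$overlap_histogram$n_pairs)]
  } else {
    NA_integer_
  }
  cat("  overlap mode:", mode_o, " z10:", format(x$z10, digits = 3), "\n")
  a10 <- x$pos10_A$pos10_A_fraction
  cat("  position-10 A fraction (+/-):",
      paste(format(a10, digits = 3), collapse = " / "), "\n")
  invisible(x)
}

#' Binomial likelihood-ratio confidence interval for a strand fraction
#'
#' Point estimate `p = pos / (pos + neg)` with bounds from inverting the
#' binomial likelihood-ratio test: the interval is the set of `p` with
#' deviance `2 * (l(p_hat) - l(p))` below the chi-squared(1) quantile at
#' `conf`. Endpoints are located by bisection to 1e-9 and clamped to
#' `[0, 1]`.
#'
#' @param pos_count,neg_count Reads on the positive / negative strand.
#' @param conf Confidence level (default 0.95).
#' @return A one-row tibble with `fraction`, `lower`, `upper`.
#' @export
strand_fraction_ci <- function(pos_count, neg_count, conf = 0.95) {
  stopifnot_count(pos_count, "pos_count")
  stopifnot_count(neg_count, "neg_count")
  stopifnot_prob(conf, "conf")
  n <- pos_count + neg_count
  if (n == 0L) {
    stop("strand fraction undefined: zero total read count", call. = FALSE)
  }
  phat <- pos_count / n
  ll <- function(p) {
    t1 <- if (pos_count > 0) pos_count * log(p) else 0
    t2 <- if (neg_count > 0) neg_count * log(1 - p) else 0
    t1 + t2
  }
  thr <- ll(phat) - stats::qchisq(conf, df = 1) / 2
  bisect <- function(lo, hi, increasing) {
    # find p with ll(p) = thr; ll is monotone on each side of phat
    for (i in 1:80) {
      mid <- (lo + hi) / 2
      above <- ll(mid) >= thr
      if (above == increasing) hi <- mid else lo <- mid
      if (hi - lo < 1e-9) break
    }
    (lo + hi) / 2
  }
  lower <- if (pos_count == 0L) 0 else bisect(0, phat, increasing = TRUE)
  upper <- if (neg_count == 0L) 1 else bisect(phat, 1, increasing = FALSE)
  tibble::tibble(fraction = phat, lower = max(0, lower),
                 upper = min(1, upper))
}

#' Oxidation enrichment of a read class relative to an anchor class
#'
#' Fold change of the class:anchor count ratio between an oxidised and an
#' untreated library:
#' `(class_ox / anchor_ox) / (class_untreated / anchor_untreated)`.
#' With miRNA-mapped counts as the anchor, a fully 3' 2'-O-methylated class
#' shows a fold near `1 / f_ox` (about 300 under the default oxidation
#' retention), the hallmark of methylated viRNAs/piRNAs.
#'
#' @param class_ox,class_untreated Class-mapped read counts in the oxidised
#'   and untreated libraries.
#' @param anchor_ox,anchor_untreated Anchor-mapped (miRNA) counts; must be
#'   positive.
#' @return The fold change (numeric scalar).
#' @export
oxidation_enrichment <- function(class_ox, class_untreated, anchor_ox,
                                 anchor_untreated) {
  if (anchor_ox <= 0 || anchor_untreated <= 0) {
    stop("anchor counts must be positive in both libraries", call. = FALSE)
  }
  if (class_untreated <= 0) {
    stop("untreated class count must be positive to form a ratio",
         call. = FALSE)
  }
  (class_ox / anchor_ox) / (class_untreated / anchor_untreated)
}
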