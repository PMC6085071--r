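test_that("size profiles count alignments exactly and conserve totals", {
  empty <- size_profile(make_alignments(integer(0), integer(0),
                                        character(0)))
  expect_equal(sum(empty$n), 0)
  expect_equal(nrow(empty), 24 * 2 * 4)

  aln <- make_alignments(c(10, 40, 100), c(31, 61, 128),
                         c("+", "+", "-"),
                         seq = c(paste0("T", random_seq(20)),
                                 paste0("T", random_seq(20)),
                                 paste0("A", random_seq(27))))
  prof <- size_profile(aln)
  expect_equal(prof$n[prof$length == 21 & prof$strand == "+" &
                        prof$base == "U"], 2)
  expect_equal(prof$n[prof$length == 28 & prof$strand == "-" &
                        prof$base == "A"], 1)
  expect_equal(sum(prof$n), 3)
  ml <- modal_length(prof)
  expect_equal(ml$modal_length[ml$strand == "+"], 21)
})

test_that("modal length recovery from mapped dicer reads, ties to smaller", {
  ctg <- sim_contig(2000, 0.5, seed = 41)
  reads <- sim_small_reads(ctg, srna_model("dicer_siRNA"), 4000, seed = 42)
  aln <- map_reads(reads, ctg, max_mismatch = 1)
  ml <- modal_length(size_profile(aln))
  expect_equal(ml$modal_length, c(21L, 21L))

  tied <- size_profile(make_alignments(c(0, 0), c(21, 28), c("+", "+")))
  expect_equal(modal_length(tied)$modal_length[1], 21)
})

test_that("positional coverage accumulates 5' ends per strand", {
  aln <- make_alignments(c(10, 10), c(31, 31), c("+", "-"))
  cov <- positional_coverage(aln, 50)
  expect_equal(cov$pos_starts[cov$position == 10], 1)
  expect_equal(cov$neg_starts[cov$position == 30], 1)
  expect_equal(sum(cov$pos_starts), 1)
  expect_equal(sum(cov$neg_starts), 1)
  expect_error(positional_coverage(aln, 20), "contig_length")
})

test_that("hotspot generation concentrates 5' starts relative to uniform", {
  ctg <- sim_contig(2000, 0.5, seed = 51)
  hot <- sim_small_reads(ctg, srna_model("primary_piRNA",
                                         hotspot_concentration = 0.05),
                         3000, seed = 52)
  flat <- sim_small_reads(ctg, srna_model("primary_piRNA",
                                          hotspot_concentration = 1e6),
                          3000, seed = 52)
  cov_of <- function(reads) {
    aln <- map_reads(reads, ctg, max_mismatch = 1)
    cov <- positional_coverage(aln[!duplicated(aln$read_id), ], 2000)
    cov$pos_starts + cov$neg_starts
  }
  expect_gt(gini_coef(cov_of(hot)), gini_coef(cov_of(flat)))
})

test_that("sequence logo information content matches analytic cases", {
  same <- make_alignments(rep(0, 4), rep(20, 4), rep("+", 4),
                          seq = rep(strrep("A", 20), 4))
  same$read_id <- sprintf("r%d", 1:4)
  same$seq <- c("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGT",
                "ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGT")
  logo <- sequence_logo(same, "+")
  expect_equal(attr(logo, "n_unique"), 1)
  expect_true(all(abs(logo$ic - 2) < 1e-12))

  tail16 <- strrep("ACGT", 4)
  mixed <- make_alignments(rep(0, 4), rep(20, 4), rep("+", 4),
                           seq = paste0(c("A", "C", "G", "T"), "CGT",
                                        tail16))
  logo <- sequence_logo(mixed, "+")
  expect_equal(unique(logo$ic[logo$position == 1]), 0)

  half <- make_alignments(rep(0, 2), rep(20, 2), rep("+", 2),
                          seq = paste0(c("T", "A"), "CGT", tail16))
  logo <- sequence_logo(half, "+")
  expect_equal(unique(logo$ic[logo$position == 1]), 1)
  expect_equal(sort(logo$freq[logo$position == 1 &
                                logo$base %in% c("A", "U")]), c(0.5, 0.5))

  expect_equal(nrow(sequence_logo(mixed, "-")), 0)
})

test_that("logo information content is invariant under base relabelling", {
  withr::local_seed(61)
  seqs <- replicate(30, random_seq(21))
  aln <- make_alignments(rep(0, 30), rep(21, 30), rep("+", 30), seq = seqs)
  ic1 <- unique(sequence_logo(aln, "+")[, c("position", "ic")])
  aln2 <- aln
  aln2$seq <- chartr("ACGT", "GTAC", aln$seq)
  ic2 <- unique(sequence_logo(aln2, "+")[, c("position", "ic")])
  expect_equal(ic1$ic, ic2$ic)
  expect_true(all(ic1$ic >= 0 & ic1$ic <= 2))
})

test_that("the 5'-overlap convention matches the canonical single pair", {
  # + read 5' at s = 100, - read 5' at s + 9 = 109: overlap exactly 10
  aln <- make_alignments(c(100, 85), c(125, 110), c("+", "-"))
  pp <- ping_pong_signature(aln)
  expect_equal(pp$overlap_histogram$n_pairs[pp$overlap_histogram$overlap ==
                                              10], 1)
  expect_equal(pp$n_pairs, 1)

  # one strand only: no pairs, z10 undefined
  solo <- make_alignments(c(10, 50), c(31, 71), c("+", "+"))
  pp <- ping_pong_signature(solo)
  expect_equal(pp$n_pairs, 0)
  expect_true(is.na(pp$z10))
})

test_that("overlap histogram equals brute-force pair enumeration", {
  withr::local_seed(71)
  n <- 120
  strand <- sample(c("+", "-"), n, replace = TRUE)
  len <- sample(20:29, n, replace = TRUE)
  p5 <- sample(0:400, n, replace = TRUE)
  start <- ifelse(strand == "+", p5, p5 - len + 1)
  keep <- start >= 0
  aln <- make_alignments(start[keep], start[keep] + len[keep], strand[keep])
  pp <- ping_pong_signature(aln)
  # dumb O(n^2) enumeration
  want <- integer(30)
  idx_p <- which(aln$strand == "+")
  idx_n <- which(aln$strand == "-")
  p5v <- ifelse(aln$strand == "+", aln$start, aln$end - 1)
  for (i in idx_p) {
    for (j in idx_n) {
      o <- p5v[j] - p5v[i] + 1
      if (o >= 1 && o <= 30) {
        want[o] <- want[o] + 1L
      }
    }
  }
  expect_equal(pp$overlap_histogram$n_pairs, want)
})

test_that("ping-pong simulation yields overlap mode 10, high z10 and A10", {
  ctg <- sim_contig(2000, 0.5, seed = 81)
  reads <- sim_small_reads(ctg, srna_model("pingpong_piRNA",
                                           strand_fraction_pos = 0),
                           3000, seed = 82)
  aln <- map_reads(reads, ctg, max_mismatch = 1)
  pp <- ping_pong_signature(aln[!duplicated(aln$read_id), ])
  hist <- pp$overlap_histogram
  expect_equal(hist$overlap[which.max(hist$n_pairs)], 10)
  expect_gt(pp$z10, 3)
  # secondaries sit opposite 5'U primaries, so position 10 of the secondary
  # (+) strand complements the primaries' 5'U probability of 0.9
  a10 <- pp$pos10_A$pos10_A_fraction[pp$pos10_A$strand == "+"]
  expect_lt(abs(a10 - 0.9), 3 * sqrt(0.9 * 0.1 / 1500) + 0.01)
})

test_that("strand-fraction LRT interval matches boundaries and grid oracle", {
  top <- strand_fraction_ci(25, 0)
  expect_equal(top$fraction, 1)
  expect_equal(top$upper, 1)
  bot <- strand_fraction_ci(0, 25)
  expect_equal(bot$fraction, 0)
  expect_equal(bot$lower, 0)
  expect_error(strand_fraction_ci(0, 0), "zero")

  ci <- strand_fraction_ci(50, 50)
  expect_equal(ci$fraction, 0.5)
  expect_equal(ci$lower, 1 - ci$upper, tolerance = 1e-6)
  grid <- oracle_binom_ci_grid(50, 50)
  expect_lt(abs(ci$lower - grid["lower"]), 2e-6)
  expect_lt(abs(ci$upper - grid["upper"]), 2e-6)
})

test_that("strand-fraction intervals contain the estimate and shrink with n", {
  widths <- vapply(c(20, 200, 2000), function(n) {
    ci <- strand_fraction_ci(round(0.7 * n), n - round(0.7 * n))
    expect_gte(ci$fraction, ci$lower)
    expect_lte(ci$fraction, ci$upper)
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("oxidation enrichment arithmetic and error cases", {
  expect_equal(oxidation_enrichment(100, 100, 10, 10), 1)
  expect_equal(oxidation_enrichment(100, 100, 10, 1000), 100)
  expect_error(oxidation_enrichment(100, 100, 0, 10), "anchor")
})

test_that("oxidised libraries enrich methylated classes about 1/f_ox-fold", {
  ctg <- sim_contig(1500, 0.5, seed = 91)
  virna <- sim_small_reads(ctg, srna_model("dicer_siRNA",
                                           methylation_prob = 1),
                           3000, seed = 92)
  mirna <- sim_small_reads(ctg, srna_model("miRNA", methylation_prob = 0),
                           30000, seed = 93)
  folds <- vapply(1:8, function(s) {
    ox_v <- nrow(apply_library_treatment(virna, "oxidised", f_ox = 1 / 20,
                                         seed = s))
    ox_m <- nrow(apply_library_treatment(mirna, "oxidised", f_ox = 1 / 20,
                                         seed = s + 100))
    oxidation_enrichment(ox_v, nrow(virna), ox_m, nrow(mirna))
  }, numeric(1))
  expect_lt(abs(mean(folds) - 20), 3 * stats::sd(folds) / sqrt(8) + 1)
})

test_that("z10 behaves as a null statistic for strand-symmetric reads", {
  withr::local_seed(99)
  z <- vapply(1:40, function(i) {
    n <- 200
    strand <- rep(c("+", "-"), each = n / 2)
    len <- sample(24:28, n, replace = TRUE)
    p5 <- sample(30:960, n, replace = TRUE)
    start <- ifelse(strand == "+", p5, p5 - len + 1)
    pp <- ping_pong_signature(make_alignments(start, start + len, strand))
    pp$z10
  }, numeric(1))
  expect_lt(abs(mean(z, na.rm = TRUE)), 0.5)
})
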