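test_that("length filter keeps exactly the 17-40 nt window, order preserved", {
  reads <- tibble::tibble(
    read_id = c("a", "b", "c", "d", "e"),
    seq = c(strrep("A", 16), strrep("A", 17), strrep("A", 40),
            strrep("A", 41), strrep("A", 25)))
  kept <- filter_read_length(reads)
  expect_identical(kept$read_id, c("b", "c", "e"))
  expect_equal(nrow(filter_read_length(reads[0, ])), 0)
  expect_error(filter_read_length(reads, 30, 20), "min_len")
})

test_that("exact substrings and reverse complements map where planted", {
  withr::local_seed(101)
  cseq <- random_seq(300)
  ctg <- tibble::tibble(contig_id = "c1", sequence = cseq, length = 300L)
  fwd <- tibble::tibble(read_id = "f", seq = substr(cseq, 11, 31))
  aln <- map_reads(fwd, ctg, mode = "exact")
  expect_equal(nrow(aln), 1)
  expect_equal(aln$start, 10)
  expect_equal(aln$end, 31)
  expect_equal(aln$strand, "+")
  expect_equal(aln$mismatches, 0)

  rev <- tibble::tibble(read_id = "r", seq = rc_chr(substr(cseq, 51, 71)))
  aln <- map_reads(rev, ctg, mode = "exact")
  expect_equal(nrow(aln), 1)
  expect_equal(aln$start, 50)
  expect_equal(aln$strand, "-")

  expect_error(map_reads(fwd, ctg, mode = "nonsense"))
})

test_that("an N base counts as a mismatch", {
  ctg <- tibble::tibble(contig_id = "c1", sequence = strrep("ACGT", 20),
                        length = 80L)
  rd <- tibble::tibble(read_id = "n1",
                       seq = paste0("N", substr(ctg$sequence, 2, 20)))
  expect_equal(nrow(map_reads(rd, ctg, mode = "exact")), 0)
  aln <- map_reads(rd, ctg, max_mismatch = 1)
  expect_true(any(aln$start == 0 & aln$mismatches == 1))
})

test_that("end-to-end and exact modes equal the exhaustive Hamming oracle", {
  withr::local_seed(202)
  for (rep in 1:6) {
    cseq <- random_seq(sample(300:800, 1))
    ctg <- tibble::tibble(contig_id = "c1", sequence = cseq,
                          length = nchar(cseq))
    reads <- tibble::tibble(
      read_id = sprintf("r%03d", 1:40),
      seq = replicate(40, sample_read_from(cseq, sample(17:32, 1),
                                           n_sub = sample(0:2, 1))))
    for (mm in 0:2) {
      got <- map_reads(reads, ctg, mode = "end_to_end", max_mismatch = mm)
      for (i in seq_len(nrow(reads))) {
        want <- oracle_map_e2e(reads$seq[i], cseq, mm)
        have <- got[got$read_id == reads$read_id[i],
                    c("start", "strand", "mismatches")]
        have <- have[order(have$start, have$strand), ]
        expect_equal(unname(as.data.frame(have)), unname(want),
                     ignore_attr = TRUE)
      }
    }
  }
})

test_that("local mode equals an exhaustive soft-clip window oracle", {
  withr::local_seed(303)
  for (rep in 1:4) {
    cseq <- random_seq(400)
    ctg <- tibble::tibble(contig_id = "c1", sequence = cseq, length = 400L)
    # plant reads whose ends are corrupted so only a clipped core matches
    seqs <- replicate(30, {
      r <- sample_read_from(cseq, sample(20:32, 1), n_sub = sample(0:2, 1))
      junk <- random_seq(sample(0:4, 1))
      if (stats::runif(1) < 0.5) paste0(junk, r) else paste0(r, junk)
    })
    seqs <- substr(seqs, 1, 40)
    reads <- tibble::tibble(read_id = sprintf("r%03d", seq_along(seqs)),
                            seq = seqs)
    got <- map_reads(reads, ctg, mode = "local", max_mismatch = 2)
    for (i in seq_len(nrow(reads))) {
      want <- oracle_map_local(reads$seq[i], cseq, 2)
      have <- got[got$read_id == reads$read_id[i], ]
      if (is.null(want)) {
        expect_equal(nrow(have), 0)
      } else {
        expect_equal(nrow(have), 1)
        expect_equal(have$start, want$start)
        expect_equal(have$end - have$start, want$len)
        expect_equal(have$mismatches, want$mm)
        expect_equal(have$strand, want$strand)
      }
    }
  }
})

test_that("hit sets grow monotonically with the mismatch budget", {
  withr::local_seed(404)
  cseq <- random_seq(600)
  ctg <- tibble::tibble(contig_id = "c1", sequence = cseq, length = 600L)
  reads <- tibble::tibble(
    read_id = sprintf("r%03d", 1:30),
    seq = replicate(30, sample_read_from(cseq, 21, n_sub = sample(0:2, 1))))
  key <- function(a) paste(a$read_id, a$start, a$strand)
  prev <- character(0)
  for (mm in 0:3) {
    cur <- key(map_reads(reads, ctg, max_mismatch = mm))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("mapping a reverse-complemented read swaps strands only", {
  withr::local_seed(505)
  cseq <- random_seq(500)
  ctg <- tibble::tibble(contig_id = "c1", sequence = cseq, length = 500L)
  reads <- tibble::tibble(
    read_id = sprintf("r%03d", 1:20),
    seq = replicate(20, sample_read_from(cseq, 24, n_sub = 1)))
  flipped <- dplyr::mutate(reads, seq = vapply(seq, rc_chr, character(1)))
  a <- map_reads(reads, ctg, max_mismatch = 2)
  b <- map_reads(flipped, ctg, max_mismatch = 2)
  swap <- function(s) ifelse(s == "+", "-", "+")
  a_key <- paste(a$read_id, a$start, a$end, swap(a$strand), a$mismatches)
  b_key <- paste(b$read_id, b$start, b$end, b$strand, b$mismatches)
  expect_setequal(a_key, b_key)
})

test_that("hierarchical mapping assigns each read to the first matching set", {
  withr::local_seed(606)
  rrna <- tibble::tibble(contig_id = "rrna1", sequence = random_seq(400),
                         length = 400L)
  virus <- tibble::tibble(contig_id = "virus1", sequence = random_seq(400),
                          length = 400L)
  # a read present in both references must land in the first set only
  shared <- substr(rrna$sequence, 100, 124)
  virus$sequence <- paste0(substr(virus$sequence, 1, 200), shared,
                           substr(virus$sequence, 226, 400))
  reads <- tibble::tibble(
    read_id = c("both", "virus_only", "neither"),
    seq = c(shared, substr(virus$sequence, 10, 33), random_seq(25)))
  res <- hierarchical_map(
    reads,
    list(list(name = "rrna", contigs = rrna, policy = "first_hit"),
         list(name = "virus", contigs = virus, policy = "all_hits")))
  expect_equal(res$set[res$read_id == "both"], "rrna")
  expect_equal(res$set[res$read_id == "virus_only"], "virus")
  expect_equal(unmapped_reads(res), "neither")
  # bucket partition: every read is in exactly one bucket or unmapped
  expect_equal(length(unique(res$read_id)) + length(unmapped_reads(res)),
               nrow(reads))

  expect_error(hierarchical_map(
    reads, list(list(name = "a", contigs = rrna),
                list(name = "a", contigs = virus))), "unique")
})

test_that("all_hits keeps multiple placements of one read in one bucket", {
  core <- random_seq(25)
  cseq <- paste0(random_seq(50), core, random_seq(60), core, random_seq(40))
  ctg <- tibble::tibble(contig_id = "c1", sequence = cseq,
                        length = nchar(cseq))
  reads <- tibble::tibble(read_id = "dup", seq = core)
  res <- hierarchical_map(
    reads, list(list(name = "virus", contigs = ctg, policy = "all_hits")),
    max_mismatch = 0)
  expect_equal(nrow(res), 2)
  expect_equal(unique(res$set), "virus")
  expect_equal(sort(res$start), c(50, 135))
})
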