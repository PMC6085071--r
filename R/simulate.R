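#' Simulate a random contig
#'
#' Generates a reference contig with a given GC content. Bases are drawn
#' independently with P(G) = P(C) = `gc_fraction / 2` and
#' P(A) = P(T) = `(1 - gc_fraction) / 2`.
#'
#' @param length Contig length in nucleotides (>= 50).
#' @param gc_fraction Expected G+C fraction in `[0, 1]`.
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @param contig_id Identifier for the contig.
#' @param category One of `"virus"`, `"TE"`, `"COI"`, `"rRNA"`,
#'   `"miRNA_hairpin"`.
#' @param genome_type One of `"pos_ssRNA"`, `"neg_ssRNA"`, `"dsRNA"`,
#'   `"ssDNA"`, `"host"`, `NA`.
#'
#' @return A one-row tibble with columns `contig_id`, `sequence`, `length`,
#'   `category`, `genome_type`.
#' @export
sim_contig <- function(length, gc_fraction, seed, contig_id = "contig1",
                       category = c("virus", "TE", "COI", "rRNA",
                                    "miRNA_hairpin"),
                       genome_type = NA_character_) {
  stopifnot_count(length, "length", min = 50L)
  stopifnot_prob(gc_fraction, "gc_fraction")
  category <- match.arg(category)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seq <- withr::with_seed(seed, {
    paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
  })
  tibble::tibble(contig_id = contig_id, sequence = seq, length = length,
                 category = category, genome_type = genome_type)
}

#' Small-RNA generative model specification
#'
#' Parameterises one of five generative classes of small RNA. Read lengths are
#' a discretised normal (rounded, clamped to 17--40 nt) except for the
#' degradation model, whose lengths decay geometrically from 17 nt upward
#' (P(L) proportional to `degradation_decay^(L - 17)`).
#'
#' Defaults reflect the signatures the classes are expected to leave:
#' Dicer siRNA duplexes peak sharply at 21 nt with a 2 nt 3' overhang and a
#' 3' 2'-O-methyl group; primary piRNAs peak broadly at 28 nt with a strong
#' 5' U bias, one dominant strand, and 3' methylation; ping-pong secondary
#' piRNAs sit opposite a 5'U primary with exactly 10 nt of 5'-to-5' overlap
#' (hence an A at read position 10); degradation fragments are short,
#' positionally uniform and unmethylated; miRNAs arise from a near-point
#' hotspot on one strand and are unmethylated (so depleted by oxidation).
#'
#' @param model Generative class.
#' @param length_mode,length_sd Centre and spread of the length distribution
#'   (nt); `length_mode` must lie in 17--40.
#' @param five_prime_U_prob Probability that the 5' base of a read is U. The
#'   5' base is resampled for every read (U with this probability, otherwise
#'   uniform over A/C/G) so the realised 5'U fraction equals the parameter;
#'   this touches the 5' position only, keeping reads mappable with at most
#'   one mismatch.
#' @param strand_fraction_pos Probability a read derives from the + strand
#'   (ignored by the duplex-paired dicer model; the degradation default of 1
#'   follows transcript sense). For the ping-pong model this is the
#'   probability that the *primary* of a pair lies on the + strand, so the
#'   default 0.05 yields 5'U primaries on the - strand and A10 secondaries
#'   on the + strand, the canonical layout.
#' @param hotspot_concentration Symmetric Dirichlet concentration over 5'-end
#'   start positions; small values give strong positional hotspots.
#' @param duplex_overhang 3' overhang of each read over its duplex partner's
#'   5' end (dicer model only).
#' @param methylation_prob Probability a read carries a 3' 2'-O-methyl group
#'   (protects it from periodate oxidation).
#' @param triphosphate_prob Probability a read carries a 5' triphosphate
#'   (makes it unligatable except after polyphosphatase treatment).
#' @param degradation_decay Geometric decay rate of degradation lengths.
#'
#' @return A list of class `srna_model`.
#' @export
srna_model <- function(model = c("dicer_siRNA", "primary_piRNA",
                                 "pingpong_piRNA", "degradation", "miRNA"),
                       length_mode = NULL, length_sd = NULL,
                       five_prime_U_prob = NULL, strand_fraction_pos = NULL,
                       hotspot_concentration = NULL, duplex_overhang = 2L,
                       methylation_prob = NULL, triphosphate_prob = 0,
                       degradation_decay = 0.65) {
  model <- match.arg(model)
  defaults <- switch(model,
    dicer_siRNA = list(length_mode = 21, length_sd = 0.75,
                       five_prime_U_prob = 0.9, strand_fraction_pos = 0.5,
                       hotspot_concentration = 0.5, methylation_prob = 1),
    primary_piRNA = list(length_mode = 28, length_sd = 1.5,
                         five_prime_U_prob = 0.9, strand_fraction_pos = 0.05,
                         hotspot_concentration = 0.2, methylation_prob = 1),
    pingpong_piRNA = list(length_mode = 28, length_sd = 1.5,
                          five_prime_U_prob = 0.9, strand_fraction_pos = 0.05,
                          hotspot_concentration = 0.2, methylation_prob = 1),
    degradation = list(length_mode = 17, length_sd = 0,
                       five_prime_U_prob = 0.25, strand_fraction_pos = 1,
                       hotspot_concentration = 1e6, methylation_prob = 0),
    miRNA = list(length_mode = 22, length_sd = 0.5,
                 five_prime_U_prob = 0.8, strand_fraction_pos = 1,
                 hotspot_concentration = 0.005, methylation_prob = 0)
  )
  spec <- list(
    model = model,
    length_mode = length_mode %||% defaults$length_mode,
    length_sd = length_sd %||% defaults$length_sd,
    five_prime_U_prob = five_prime_U_prob %||% defaults$five_prime_U_prob,
    strand_fraction_pos = strand_fraction_pos %||%
      defaults$strand_fraction_pos,
    hotspot_concentration = hotspot_concentration %||%
      defaults$hotspot_concentration,
    duplex_overhang = duplex_overhang,
    methylation_prob = methylation_prob %||% defaults$methylation_prob,
    triphosphate_prob = triphosphate_prob,
    degradation_decay = degradation_decay
  )
  stopifnot_prob(spec$five_prime_U_prob, "five_prime_U_prob")
  stopifnot_prob(spec$strand_fraction_pos, "strand_fraction_pos")
  stopifnot_prob(spec$methylation_prob, "methylation_prob")
  stopifnot_prob(spec$triphosphate_prob, "triphosphate_prob")
  if (spec$length_mode < 17 || spec$length_mode > 40) {
    stop("`length_mode` must lie in 17-40 nt", call. = FALSE)
  }
  if (spec$length_sd < 0) stop("`length_sd` must be >= 0", call. = FALSE)
  if (spec$duplex_overhang < 0) {
    stop("`duplex_overhang` must be >= 0", call. = FALSE)
  }
  if (spec$hotspot_concentration <= 0) {
    stop("`hotspot_concentration` must be > 0", call. = FALSE)
  }
  structure(spec, class = "srna_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# discretised read lengths, clamped to the 17-40 nt window
draw_lengths <- function(n, spec) {
  if (spec$model == "degradation") {
    l <- 17L + stats::rgeom(n, prob = 1 - spec$degradation_decay)
  } else {
    l <- round(stats::rnorm(n, spec$length_mode, spec$length_sd))
  }
  pmin(pmax(as.integer(l), 17L), 40L)
}

# per-contig Dirichlet hotspot weights for 5'-end positions; seeded from the
# contig id (not the run seed) so hotspots repeat across libraries and runs
hotspot_weights <- function(contig_id, contig_length, concentration,
                            hotspot_seed = NULL) {
  hseed <- hotspot_seed %||% hash31(contig_id)
  withr::with_seed(hseed, {
    w_pos <- stats::rgamma(contig_length, shape = concentration) + 1e-12
    w_neg <- stats::rgamma(contig_length, shape = concentration) + 1e-12
    list(pos = w_pos / sum(w_pos), neg = w_neg / sum(w_neg))
  })
}

# resample the 5' base: U with probability q, otherwise uniform over A/C/G
force_five_prime <- function(seqs, q) {
  n <- length(seqs)
  is_u <- stats::runif(n) < q
  newb <- ifelse(is_u, "T", sample(c("A", "C", "G"), n, replace = TRUE))
  substr(seqs, 1L, 1L) <- newb
  seqs
}

complement1 <- function(base) chartr("ACGT", "TGCA", base)

#' Simulate small-RNA reads from a contig
#'
#' Draws reads from one generative class (see [srna_model()]). Every read is a
#' substring of the contig or its reverse complement, except that the 5' base
#' is resampled (and, for ping-pong secondaries, position 10 is set to the
#' complement of the partner primary's 5' base), so every read maps back to
#' its source with at most one mismatch.
#'
#' Dicer reads come in sense/antisense duplex pairs whose 3' ends overhang the
#' partner's 5' end by `duplex_overhang` nt. Ping-pong reads come in
#' primary/secondary pairs on opposite strands with exactly 10 nt of 5'-to-5'
#' overlap. 5'-end positions are drawn from contig-specific Dirichlet hotspot
#' weights (uniform for the degradation model).
#'
#' @param contig One-row contig tibble from [sim_contig()] (or with at least
#'   `contig_id` and `sequence`).
#' @param spec An [srna_model()] specification.
#' @param n_reads Number of reads to generate (>= 0).
#' @param seed Integer seed.
#' @param library_id Library label stored on each read.
#' @param hotspot_seed Optional override for the hotspot weight seed.
#'
#' @return A tibble of reads with columns `read_id`, `seq`, `library_id` and
#'   the truth-only columns `truth_class`, `has_5p_triphosphate`,
#'   `has_3p_2ome`, `source_contig`, `source_strand`. Truth columns are for
#'   validation; the analysis functions never read them.
#' @export
sim_small_reads <- function(contig, spec, n_reads, seed,
                            library_id = "lib1", hotspot_seed = NULL) {
  if (!inherits(spec, "srna_model")) {
    stop("`spec` must be an `srna_model` object", call. = FALSE)
  }
  stopifnot_count(n_reads, "n_reads")
  cseq <- contig$sequence[[1]]
  cid <- contig$contig_id[[1]]
  lc <- nchar(cseq)
  if (lc <= spec$length_mode + 5) {
    stop("contig too short for the configured read lengths", call. = FALSE)
  }
  if (n_reads == 0L) return(empty_reads(library_id))
  w <- hotspot_weights(cid, lc, spec$hotspot_concentration, hotspot_seed)
  out <- withr::with_seed(seed, {
    switch(spec$model,
      dicer_siRNA = sim_dicer(cseq, spec, n_reads, w),
      pingpong_piRNA = sim_pingpong(cseq, spec, n_reads, w),
      degradation = sim_single(cseq, spec, n_reads, w, uniform = TRUE),
      sim_single(cseq, spec, n_reads, w, uniform = FALSE)
    )
  })
  out$read_id <- sprintf("%s_%s_%06d", library_id, spec$model,
                         seq_len(nrow(out)))
  out$library_id <- library_id
  out$truth_class <- spec$model
  out$source_contig <- cid
  dplyr::select(out, "read_id", "seq", "library_id", "truth_class",
                "has_5p_triphosphate", "has_3p_2ome", "source_contig",
                "source_strand")
}

empty_reads <- function(library_id = character(0)) {
  tibble::tibble(read_id = character(0), seq = character(0),
                 library_id = character(0), truth_class = character(0),
                 has_5p_triphosphate = logical(0), has_3p_2ome = logical(0),
                 source_contig = character(0), source_strand = character(0))
}

# single-strand-logic classes: primary piRNA, miRNA, degradation
sim_single <- function(cseq, spec, n, w, uniform) {
  lc <- nchar(cseq)
  len <- draw_lengths(n, spec)
  plus <- stats::runif(n) < spec$strand_fraction_pos
  # 5' end position per read: + strand 5' = start, - strand 5' = right end
  p5 <- integer(n)
  for (i in seq_len(n)) {
    if (plus[i]) {
      hi <- lc - len[i] + 1L           # 1-based start range
      probs <- if (uniform) NULL else w$pos[seq_len(hi)]
      p5[i] <- sample.int(hi, 1L, prob = probs)
    } else {
      lo <- len[i]
      idx <- lo:lc
      probs <- if (uniform) NULL else w$neg[idx]
      p5[i] <- idx[sample.int(length(idx), 1L, prob = probs)]
    }
  }
  seq <- character(n)
  if (any(plus)) {
    seq[plus] <- substring(cseq, p5[plus], p5[plus] + len[plus] - 1L)
  }
  if (any(!plus)) {
    seq[!plus] <- revcomp(substring(cseq, p5[!plus] - len[!plus] + 1L,
                                    p5[!plus]))
  }
  seq <- force_five_prime(seq, spec$five_prime_U_prob)
  tibble::tibble(
    seq = seq,
    has_5p_triphosphate = stats::runif(n) < spec$triphosphate_prob,
    has_3p_2ome = stats::runif(n) < spec$methylation_prob,
    source_strand = ifelse(plus, "+", "-")
  )
}

# Dicer siRNA duplexes: sense read [s, s+L), antisense partner covering
# [s - overhang, s - overhang + L) on the - strand, so each 3' end overhangs
# the partner's 5' end by `duplex_overhang` nt
sim_dicer <- function(cseq, spec, n, w) {
  lc <- nchar(cseq)
  np <- ceiling(n / 2)
  len <- draw_lengths(np, spec)
  ov <- spec$duplex_overhang
  s <- integer(np)                      # 1-based sense start
  for (i in seq_len(np)) {
    idx <- (1L + ov):(lc - len[i] + 1L)
    s[i] <- idx[sample.int(length(idx), 1L, prob = w$pos[idx])]
  }
  sense <- substring(cseq, s, s + len - 1L)
  anti <- revcomp(substring(cseq, s - ov, s - ov + len - 1L))
  seqs <- as.vector(rbind(sense, anti))[seq_len(n)]
  strands <- as.vector(rbind(rep("+", np), rep("-", np)))[seq_len(n)]
  seqs <- force_five_prime(seqs, spec$five_prime_U_prob)
  tibble::tibble(
    seq = seqs,
    has_5p_triphosphate = stats::runif(n) < spec$triphosphate_prob,
    has_3p_2ome = stats::runif(n) < spec$methylation_prob,
    source_strand = strands
  )
}

# Ping-pong pairs: a 5'U-biased primary and an opposite-strand secondary with
# exactly 10 nt of 5'-to-5' overlap; position 10 of the secondary is the
# complement of the primary's (possibly resampled) 5' base
sim_pingpong <- function(cseq, spec, n, w) {
  lc <- nchar(cseq)
  np <- ceiling(n / 2)
  len1 <- draw_lengths(np, spec)
  len2 <- draw_lengths(np, spec)
  prim_plus <- stats::runif(np) < spec$strand_fraction_pos
  prim <- character(np); seco <- character(np)
  for (i in seq_len(np)) {
    L1 <- len1[i]; L2 <- len2[i]
    if (prim_plus[i]) {
      # primary + with 5' at s; secondary - with 5' at e = s + 9
      lo <- max(1L, 10L - L2 + 1L + 9L)      # need e - L2 + 1 >= 1
      lo <- max(lo, L2 - 9L)                 # i.e. s >= L2 - 9
      hi <- lc - max(L1, 10L) + 1L
      hi <- min(hi, lc - 9L)                 # e <= lc
      idx <- max(1L, lo):hi
      s <- idx[sample.int(length(idx), 1L, prob = w$pos[idx])]
      prim[i] <- substring(cseq, s, s + L1 - 1L)
      e <- s + 9L
      seco[i] <- revcomp(substring(cseq, e - L2 + 1L, e))
    } else {
      # primary - with 5' at e; secondary + with 5' at s = e - 9
      lo <- max(L1, 10L)
      hi <- min(lc, lc - (L2 - 10L))         # need s + L2 - 1 <= lc
      idx <- lo:hi
      e <- idx[sample.int(length(idx), 1L, prob = w$neg[idx])]
      prim[i] <- revcomp(substring(cseq, e - L1 + 1L, e))
      s <- e - 9L
      seco[i] <- substring(cseq, s, s + L2 - 1L)
    }
  }
  prim <- force_five_prime(prim, spec$five_prime_U_prob)
  substr(seco, 10L, 10L) <- complement1(substr(prim, 1L, 1L))
  seqs <- as.vector(rbind(prim, seco))[seq_len(n)]
  strands <- as.vector(rbind(ifelse(prim_plus, "+", "-"),
                             ifelse(prim_plus, "-", "+")))[seq_len(n)]
  tibble::tibble(
    seq = seqs,
    has_5p_triphosphate = stats::runif(n) < spec$triphosphate_prob,
    has_3p_2ome = stats::runif(n) < spec$methylation_prob,
    source_strand = strands
  )
}

#' Apply a library-treatment retention model to simulated reads
#'
#' Emulates how library preparation filters the small-RNA pool. Untreated and
#' oxidised libraries cannot ligate 5'-triphosphate reads, so those are
#' dropped (polyphosphatase converts the triphosphate and retains them).
#' Periodate oxidation additionally suppresses ligation of reads lacking a
#' 3' 2'-O-methyl group: unmethylated reads are retained independently with
#' probability `f_ox`, methylated reads always.
#'
#' @param reads Read tibble from [sim_small_reads()].
#' @param treatment `"untreated"`, `"polyphosphatase"` or `"oxidised"`.
#' @param f_ox Retention probability of unmethylated reads under oxidation.
#'   The default 1/300 reproduces a 300-fold shift of the miRNA:viRNA ratio.
#' @param seed Integer seed.
#'
#' @return The retained subset of `reads`.
#' @export
apply_library_treatment <- function(reads,
                                    treatment = c("untreated",
                                                  "polyphosphatase",
                                                  "oxidised"),
                                    f_ox = 1 / 300, seed = 1L) {
  treatment <- match.arg(treatment)
  if (f_ox <= 0 || f_ox > 1) {
    stop("`f_ox` must lie in (0, 1]", call. = FALSE)
  }
  if (treatment == "polyphosphatase") return(reads)
  kept <- !reads$has_5p_triphosphate
  if (treatment == "oxidised") {
    unmeth <- !reads$has_3p_2ome
    keep_ox <- withr::with_seed(seed, stats::runif(nrow(reads)) < f_ox)
    kept <- kept & (reads$has_3p_2ome | keep_ox)
  }
  reads[kept, , drop = FALSE]
}

#' Simulate stranded RNA-seq counts for contigs
#'
#' Total read counts are negative-binomial with the given mean and dispersion
#' (variance `mu + dispersion * mu^2`); the positive-sense count is binomial
#' given the total.
#'
#' @param contigs Contig tibble (uses `contig_id`).
#' @param mean_total Expected total read count (recycled across contigs).
#' @param dispersion Negative-binomial dispersion (> 0); values near zero
#'   approach a Poisson.
#' @param pos_fraction Probability that a read derives from the positive
#'   (sense) strand (recycled).
#' @param seed Integer seed.
#'
#' @return A tibble with `contig_id`, `pos_count`, `neg_count`.
#' @export
sim_rnaseq_counts <- function(contigs, mean_total, dispersion, pos_fraction,
                              seed) {
  if (any(mean_total < 0) || any(dispersion <= 0)) {
    stop("`mean_total` must be >= 0 and `dispersion` > 0", call. = FALSE)
  }
  if (any(pos_fraction < 0 | pos_fraction > 1)) {
    stop("`pos_fraction` must lie in [0, 1]", call. = FALSE)
  }
  n <- nrow(contigs)
  mean_total <- rep_len(mean_total, n)
  dispersion <- rep_len(dispersion, n)
  pos_fraction <- rep_len(pos_fraction, n)
  withr::with_seed(seed, {
    total <- stats::rnbinom(n, mu = mean_total, size = 1 / dispersion)
    pos <- stats::rbinom(n, total, pos_fraction)
    tibble::tibble(contig_id = contigs$contig_id, pos_count = pos,
                   neg_count = total - pos)
  })
}

#' Build the packaged five-class synthetic benchmark
#'
#' One contig per generative class with well-separated default parameters, a
#' read set of `n_reads` per contig, and stranded RNA-seq counts. The
#' `expected_label` column records the signature class the generator's truth
#' implies, for recovery testing.
#'
#' The five conditions are: an abundant +ssRNA virus producing Dicer siRNA
#' duplexes (expected `viRNA_like`); a TE producing single-strand 5'U primary
#' piRNAs (`piRNA_primary`); a TE with ping-pong pairs (`piRNA_pingpong`); a
#' virus producing abundant 26--30 nt reads with no base or strand bias, as
#' seen in the whelk (`unbiased_26_30`); and a virus yielding only
#' degradation fragments (`degradation_or_none`).
#'
#' @param seed Integer seed.
#' @param n_reads Reads per contig.
#' @param contig_length Length of every contig (bp).
#' @param library_id Library label.
#'
#' @return A list with `contigs`, `reads`, `rnaseq` and a `truth` tibble
#'   mapping `contig_id` to `truth_class` and `expected_label`.
#' @export
sim_benchmark <- function(seed, n_reads = 2000L, contig_length = 2000L,
                          library_id = "bench") {
  specs <- list(
    dicer = list(spec = srna_model("dicer_siRNA"), category = "virus",
                 genome_type = "pos_ssRNA", expected = "viRNA_like"),
    primary = list(spec = srna_model("primary_piRNA"), category = "TE",
                   genome_type = NA_character_, expected = "piRNA_primary"),
    pingpong = list(spec = srna_model("pingpong_piRNA"), category = "TE",
                    genome_type = NA_character_, expected = "piRNA_pingpong"),
    whelk = list(spec = srna_model("primary_piRNA", five_prime_U_prob = 0.25,
                                   strand_fraction_pos = 0.5),
                 category = "virus", genome_type = "neg_ssRNA",
                 expected = "unbiased_26_30"),
    degradation = list(spec = srna_model("degradation"), category = "virus",
                       genome_type = "pos_ssRNA",
                       expected = "degradation_or_none")
  )
  contigs <- dplyr::bind_rows(purrr::imap(specs, function(x, nm) {
    sim_contig(contig_length, gc_fraction = 0.45,
               seed = seed + hash31(nm) %% 10000L,
               contig_id = paste0("bench_", nm), category = x$category,
               genome_type = x$genome_type)
  }))
  reads <- dplyr::bind_rows(purrr::imap(specs, function(x, nm) {
    sim_small_reads(contigs[contigs$contig_id == paste0("bench_", nm), ],
                    x$spec, n_reads, seed = seed + hash31(nm) %% 9999L,
                    library_id = library_id)
  }))
  rnaseq <- sim_rnaseq_counts(contigs, mean_total = 2000, dispersion = 0.1,
                              pos_fraction = 0.9, seed = seed + 17L)
  truth <- tibble::tibble(
    contig_id = paste0("bench_", names(specs)),
    truth_class = unname(vapply(specs, function(x) x$spec$model,
                                character(1))),
    expected_label = unname(vapply(specs, function(x) x$expected,
                                   character(1)))
  )
  list(contigs = contigs, reads = reads, rnaseq = rnaseq, truth = truth)
}
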