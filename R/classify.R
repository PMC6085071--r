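#' Classification thresholds
#'
#' Tunable boundaries for [classify_contig()]. The quadrant boundaries
#' (`y_boundary = 1`, `x_boundary = 0.01`) place a contig among
#' viRNA-dominated versus piRNA-dominated producers; `u5_min = 0.75`
#' operationalises an "almost exclusively 5'U" strand, and `z10_min = 3` with
#' `a10_min = 0.5` a clear ping-pong signature.
#'
#' @param y_boundary Minimum 20--24 nt : 25--31 nt ratio for a viRNA call.
#' @param x_boundary Minimum sRNA : RNA-seq ratio for an abundant producer.
#' @param virna_modal,pirna_modal Inclusive modal-length windows (nt).
#' @param u5_min Minimum per-strand 5'U fraction for a primary-piRNA call.
#' @param z10_min,a10_min Ping-pong z-score and position-10 A thresholds.
#' @return A named list.
#' @export
classification_thresholds <- function(y_boundary = 1, x_boundary = 0.01,
                                      virna_modal = c(20L, 24L),
                                      pirna_modal = c(25L, 31L),
                                      u5_min = 0.75, z10_min = 3,
                                      a10_min = 0.5) {
  list(y_boundary = y_boundary, x_boundary = x_boundary,
       virna_modal = virna_modal, pirna_modal = pirna_modal,
       u5_min = u5_min, z10_min = z10_min, a10_min = a10_min)
}

#' sRNA abundance ratios and eligibility for a contig
#'
#' `x_ratio` is the count of 20--31 nt small-RNA alignments divided by the
#' total RNA-seq read count; `y_ratio` is the 20--24 nt count divided by the
#' 25--31 nt count. A contig is eligible for classification when it is longer
#' than 750 bp and produced at least `min_srna` small RNAs.
#'
#' @param profile A [size_profile()] tibble for the contig.
#' @param rnaseq One-row tibble with `pos_count`, `neg_count` (or `NULL`).
#' @param contig_length Contig length in bp.
#' @param min_length,min_srna Eligibility cut-offs (defaults 750 bp, 20
#'   reads).
#' @return One-row tibble: `eligible`, `n_srna`, `x_ratio` (`NA` when the
#'   RNA-seq total is zero or missing), `y_ratio` (`NA` when the 25--31 nt
#'   count is zero).
#' @export
srna_class_ratios <- function(profile, rnaseq, contig_length,
                              min_length = 750L, min_srna = 20L) {
  n_total <- sum(profile$n)
  n_20_31 <- sum(profile$n[profile$length >= 20 & profile$length <= 31])
  n_20_24 <- sum(profile$n[profile$length >= 20 & profile$length <= 24])
  n_25_31 <- sum(profile$n[profile$length >= 25 & profile$length <= 31])
  rn_total <- if (is.null(rnaseq) || nrow(rnaseq) == 0L) 0L else
    rnaseq$pos_count[[1]] + rnaseq$neg_count[[1]]
  tibble::tibble(
    eligible = contig_length > min_length && n_total >= min_srna,
    n_srna = n_total,
    x_ratio = if (rn_total > 0) n_20_31 / rn_total else NA_real_,
    y_ratio = if (n_25_31 > 0) n_20_24 / n_25_31 else NA_real_
  )
}

#' Classify a contig's small-RNA signature
#'
#' Applies a fixed decision cascade to a per-contig report row (built by
#' [signature_report()] or by hand). In order:
#'
#' 1. `viRNA_like` -- short-class dominated (`y_ratio` above `y_boundary`, or
#'    undefined because no 25--31 nt reads exist), modal length in the viRNA
#'    window, and abundant relative to RNA-seq (`x_ratio >= x_boundary`).
#' 2. `piRNA_pingpong` -- ping-pong z-score and position-10 A fraction (on
#'    the better strand) above threshold.
#' 3. `piRNA_primary` -- piRNA-window modal length with a strongly 5'U-biased
#'    strand.
#' 4. `unbiased_26_30` -- piRNA-window modal length, abundant, but without
#'    base bias or ping-pong (the whelk-type signature).
#' 5. `degradation_or_none` otherwise.
#'
#' @param report One-row tibble/list with `eligible`, `x_ratio`, `y_ratio`,
#'   `modal_length_pos`, `modal_length_neg`, `five_prime_U_pos`,
#'   `five_prime_U_neg`, `z10`, `pos10_A_max`.
#' @param thresholds A [classification_thresholds()] list.
#' @return The label, one of `"viRNA_like"`, `"piRNA_pingpong"`,
#'   `"piRNA_primary"`, `"unbiased_26_30"`, `"degradation_or_none"`.
#' @export
classify_contig <- function(report, thresholds = classification_thresholds()) {
  if (!isTRUE(report$eligible)) {
    stop("contig is not eligible for classification ",
         "(needs > 750 bp and >= 20 mapped small RNAs)", call. = FALSE)
  }
  th <- thresholds
  # dominant modal length: the strand with more alignments decides; fall back
  # to whichever strand has one
  modal <- c(report$modal_length_pos, report$modal_length_neg)
  modal <- modal[!is.na(modal)]
  modal_dom <- if (length(modal)) modal[[1]] else NA_integer_
  if (!is.na(report$modal_length_neg) && !is.na(report$modal_length_pos) &&
      isTRUE(report$n_neg > report$n_pos)) {
    modal_dom <- report$modal_length_neg
  } else if (is.na(report$modal_length_pos)) {
    modal_dom <- report$modal_length_neg
  }
  x <- report$x_ratio
  y <- report$y_ratio
  u5 <- max(report$five_prime_U_pos, report$five_prime_U_neg, na.rm = TRUE)
  in_win <- function(l, w) !is.na(l) && l >= w[1] && l <= w[2]
  if ((is.na(y) || y > th$y_boundary) && in_win(modal_dom, th$virna_modal) &&
      !is.na(x) && x >= th$x_boundary) {
    return("viRNA_like")
  }
  if (!is.na(report$z10) && report$z10 >= th$z10_min &&
      !is.na(report$pos10_A_max) && report$pos10_A_max >= th$a10_min) {
    return("piRNA_pingpong")
  }
  if (in_win(modal_dom, th$pirna_modal) && is.finite(u5) && u5 >= th$u5_min) {
    return("piRNA_primary")
  }
  if (in_win(modal_dom, th$pirna_modal) && !is.na(x) && x >= th$x_boundary) {
    return("unbiased_26_30")
  }
  "degradation_or_none"
}

#' Assess replication / EVE status from stranded RNA-seq counts
#'
#' Uses the likelihood-ratio confidence interval of the positive-sense read
#' fraction ([strand_fraction_ci()]). A negative-sense RNA virus is called
#' replicating when the lower bound exceeds 0 (its genome alone yields no
#' positive-sense reads); a dsRNA virus when the lower bound exceeds 0.5; a
#' positive-sense RNA virus when the upper bound falls below 1 (detectable
#' negative-sense replication intermediates -- a conservative test, since
#' +ssRNA strand ratios can be extreme). An ssDNA (parvovirus-like) contig
#' whose upper bound falls below 0.5 is flagged a putative expressed
#' endogenous viral element; above 0.5 from below, it is called replicating.
#'
#' @param genome_type One of `"pos_ssRNA"`, `"neg_ssRNA"`, `"dsRNA"`,
#'   `"ssDNA"`, `"host"`, `NA`.
#' @param pos_count,neg_count Stranded RNA-seq read counts.
#' @param conf Confidence level.
#' @return `"replicating"`, `"putative_EVE"`, or `"no_evidence"`.
#' @export
replication_assessment <- function(genome_type, pos_count, neg_count,
                                   conf = 0.95) {
  if (is.na(genome_type) || genome_type %in% c("host", "NA")) {
    return("no_evidence")
  }
  if (pos_count + neg_count == 0L) {
    stop("replication assessment undefined: zero total read count",
         call. = FALSE)
  }
  ci <- strand_fraction_ci(pos_count, neg_count, conf)
  switch(genome_type,
    neg_ssRNA = if (ci$lower > 0) "replicating" else "no_evidence",
    dsRNA = if (ci$lower > 0.5) "replicating" else "no_evidence",
    pos_ssRNA = if (ci$upper < 1) "replicating" else "no_evidence",
    ssDNA = if (ci$upper < 0.5) "putative_EVE" else
      if (ci$lower > 0.5) "replicating" else "no_evidence",
    "no_evidence"
  )
}

#' Virus abundance as a percentage of host COI
#'
#' Length-normalised read count of a virus contig relative to the host's
#' cytochrome oxidase I contig:
#' `100 * (virus_total / virus_length) / (coi_total / coi_length)`.
#' Viruses below `min_percent` (default 0.01%) are flagged excluded, the
#' cut-off used when plotting relative abundances.
#'
#' @param virus_counts,coi_counts One-row tibbles with `pos_count`,
#'   `neg_count`.
#' @param virus_length,coi_length Contig lengths (bp).
#' @param min_percent Inclusion cut-off (percent of COI).
#' @return One-row tibble: `percent_of_coi`, `included`.
#' @export
relative_abundance <- function(virus_counts, virus_length, coi_counts,
                               coi_length, min_percent = 0.01) {
  coi_total <- coi_counts$pos_count[[1]] + coi_counts$neg_count[[1]]
  if (coi_total <= 0) {
    stop("COI read count must be positive", call. = FALSE)
  }
  virus_total <- virus_counts$pos_count[[1]] + virus_counts$neg_count[[1]]
  pct <- 100 * (virus_total / virus_length) / (coi_total / coi_length)
  tibble::tibble(percent_of_coi = pct, included = pct >= min_percent)
}

#' Cross-taxon contamination fractions from COI counts
#'
#' Expresses each taxon's COI read count as a fraction of the target host's
#' own COI count, the standard check that non-target taxa (commensals,
#' contaminants) contribute negligibly.
#'
#' @param coi_counts Tibble with `taxon` and `count`.
#' @param target_taxon The intended host; must have a positive count.
#' @return Tibble with `taxon` and `fraction` (target maps to 1).
#' @export
contamination_table <- function(coi_counts, target_taxon) {
  tgt <- coi_counts$count[coi_counts$taxon == target_taxon]
  if (length(tgt) != 1L || tgt <= 0) {
    stop("target taxon must be present with a positive COI count",
         call. = FALSE)
  }
  tibble::tibble(taxon = coi_counts$taxon,
                 fraction = coi_counts$count / tgt)
}

#' Per-contig signature report
#'
#' Assembles, for every contig with alignments, the statistics behind the
#' size-distribution, coverage and ping-pong panels plus the quadrant ratios,
#' then applies [classify_contig()] (eligible contigs only) and, where
#' stranded RNA-seq counts and a genome type are available,
#' [strand_fraction_ci()] and [replication_assessment()].
#'
#' @param alignments Alignment tibble (multiple contigs allowed).
#' @param contigs Contig tibble with `contig_id`, `length`, and optionally
#'   `genome_type`.
#' @param rnaseq Tibble of stranded RNA-seq counts (`contig_id`,
#'   `pos_count`, `neg_count`), or `NULL`.
#' @param thresholds A [classification_thresholds()] list.
#' @param conf Confidence level for strand-bias intervals.
#' @return A tibble with one row per contig: alignment totals per strand,
#'   modal lengths, 5'U fractions, `z10`, `pos10_A_max`, ratios,
#'   eligibility, `label` (`NA` for ineligible contigs), strand fraction and
#'   CI, and `replication_call`.
#' @export
signature_report <- function(alignments, contigs, rnaseq = NULL,
                             thresholds = classification_thresholds(),
                             conf = 0.95) {
  purrr::map_dfr(unique(alignments$contig_id), function(cid) {
    aln <- alignments[alignments$contig_id == cid, , drop = FALSE]
    cinfo <- contigs[contigs$contig_id == cid, , drop = FALSE]
    clen <- if (nrow(cinfo)) cinfo$length[[1]] else NA_integer_
    gtype <- if (nrow(cinfo) && "genome_type" %in% names(cinfo)) {
      cinfo$genome_type[[1]]
    } else {
      NA_character_
    }
    rn <- if (is.null(rnaseq)) NULL else
      rnaseq[rnaseq$contig_id == cid, , drop = FALSE]
    prof <- size_profile(aln)
    ml <- modal_length(prof)
    u5 <- five_prime_u_fraction(prof)
    pp <- ping_pong_signature(aln)
    ratios <- srna_class_ratios(prof, rn, clen)
    row <- tibble::tibble(
      contig_id = cid,
      contig_length = clen,
      n_srna = nrow(aln),
      n_pos = sum(aln$strand == "+"),
      n_neg = sum(aln$strand == "-"),
      modal_length_pos = ml$modal_length[ml$strand == "+"],
      modal_length_neg = ml$modal_length[ml$strand == "-"],
      five_prime_U_pos = u5$five_prime_U_fraction[u5$strand == "+"],
      five_prime_U_neg = u5$five_prime_U_fraction[u5$strand == "-"],
      z10 = pp$z10,
      n_pairs = pp$n_pairs,
      pos10_A_max = suppressWarnings(
        max(pp$pos10_A$pos10_A_fraction, na.rm = TRUE)),
      eligible = ratios$eligible,
      x_ratio = ratios$x_ratio,
      y_ratio = ratios$y_ratio
    )
    row$pos10_A_max[!is.finite(row$pos10_A_max)] <- NA_real_
    row$label <- if (row$eligible) classify_contig(row, thresholds) else
      NA_character_
    if (!is.null(rn) && nrow(rn) &&
        rn$pos_count[[1]] + rn$neg_count[[1]] > 0) {
      ci <- strand_fraction_ci(rn$pos_count[[1]], rn$neg_count[[1]], conf)
      row$strand_fraction <- ci$fraction
      row$strand_lower <- ci$lower
      row$strand_upper <- ci$upper
      row$replication_call <- replication_assessment(
        gtype, rn$pos_count[[1]], rn$neg_count[[1]], conf)
    } else {
      row$strand_fraction <- NA_real_
      row$strand_lower <- NA_real_
      row$strand_upper <- NA_real_
      row$replication_call <- NA_character_
    }
    row
  })
}
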