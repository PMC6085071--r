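---
title: "Profiling small-RNA defence signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling small-RNA defence signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(srnasig)
library(dplyr)
```

# The problem

Antiviral RNA interference and the piRNA pathway each leave a characteristic
fingerprint in the pool of 17–40 nt small RNAs of an organism. Dicer cleavage
of viral double-stranded RNA yields virus-derived siRNAs (viRNAs) with a
sharp length peak near 21 nt, reads from both strands, and often a 5'
uridine; primary piRNAs form a broad 26–30 nt peak on one strand with a
strong 5'U; ping-pong amplification adds opposite-strand secondary piRNAs
whose 5' ends overlap the primary's by exactly 10 nt, putting an adenine at
read position 10; and non-specific degradation yields short fragments with
no defined size structure. Because piRNAs and viRNAs typically carry a
3' 2'-O-methyl group, periodate (NaIO₄) oxidation of a library before
ligation suppresses unmethylated species (such as most animal miRNAs) and
enriches the methylated classes; polyphosphatase treatment instead makes
directly synthesised 5'-triphosphate RNAs ligatable.

`srnasig` turns these fingerprints into per-contig statistics and a
classification, starting from contig FASTA, small-RNA reads and stranded
RNA-seq counts. A seeded synthetic-data generator produces datasets with
known truth labels, so the whole pipeline can be exercised and validated
without any sequencing data. A separate module estimates per-individual
virus prevalence from pooled RT-PCR surveys by maximum likelihood.

# The synthetic-data generator

The generator is first-class, tested code: its defaults define the study
conditions that every downstream recovery test uses.

Each of the five generative classes is parameterised by `srna_model()`:

| model | length mode (sd) | 5'U prob | strands | 3'-2'-O-me | hotspots |
|---|---|---|---|---|---|
| `dicer_siRNA` | 21 (0.75) | 0.9 | duplex pairs | 1 | moderate (0.5) |
| `primary_piRNA` | 28 (1.5) | 0.9 | 5% `+` | 1 | strong (0.2) |
| `pingpong_piRNA` | 28 (1.5) | 0.9 (primaries) | paired | 1 | strong (0.2) |
| `degradation` | 17 + geometric(r = 0.65) | 0.25 | sense | 0 | uniform |
| `miRNA` | 22 (0.5) | 0.8 | `+` only | 0 | near-point (0.005) |

Numerical choices, and why:

* **Lengths** are a discretised normal (rounded, clamped to 17–40 nt),
  because observed class signatures are reported as a mode and a spread; the
  degradation class instead decays geometrically from 17 nt upward
  (`P(L) ∝ 0.65^(L−17)`), matching the enrichment of 17–19 nt fragments with
  no defined peak that distinguishes degradation from active biogenesis.
* **5' base**: the 5' nucleotide of every read is resampled — U with the
  configured probability, otherwise uniform over A/C/G — so the realised 5'U
  fraction equals the parameter exactly. Only the 5' position is touched,
  which keeps every read mappable to its source with at most one mismatch;
  this mirrors the mismatch tolerance of the mapper rather than resampling
  read positions until a U is found (which would distort the hotspot
  distribution).
* **Dicer duplexes**: a sense read `[s, s+L)` is paired with an antisense
  partner covering `[s−2, s−2+L)`, giving each 3' end the canonical 2 nt
  overhang over the partner's 5' end. The true overhang geometry of
  non-model Dicers is unknown; 2 nt is the canonical assumption and is
  configurable (`duplex_overhang`).
* **Ping-pong pairs**: a 5'U-biased primary is placed first; the secondary
  lies on the opposite strand with exactly 10 nt of 5'-to-5' overlap, and
  its position 10 is set to the complement of the primary's (possibly
  resampled) 5' base — the mechanism that produces the position-10 A mark.
  By default primaries sit on the `−` strand (`strand_fraction_pos = 0.05`
  is the probability the primary is on `+`), the canonical antisense layout.
* **Hotspots**: 5'-end positions are drawn from a symmetric-Dirichlet weight
  vector per contig and strand. The Dirichlet is seeded from a hash of the
  contig identifier, not from the run seed, so the hotspot pattern of a
  contig repeats across libraries and runs — reproducing the observed
  repeatability of hotspot patterns — while read sampling itself remains
  governed by the run seed.
* **Library treatments** act as retention filters: untreated and oxidised
  libraries drop 5'-triphosphate reads (polyphosphatase retains them);
  oxidation additionally retains unmethylated reads with probability
  `f_ox = 1/300` by default, the value that reproduces a 300-fold shift in
  the miRNA:viRNA ratio when miRNAs are unmethylated and viRNAs methylated.
* **RNA-seq counts** are negative-binomial totals (mean and dispersion, with
  variance `μ + αμ²`) split binomially between strands; counts suffice for
  every downstream statistic, so full RNA-seq reads are never simulated.

What the generator does *not* emulate: sequencing error beyond the 5'-base
substitution, adapter remnants, ADAR-style editing along the read body,
cross-mapping between near-identical contig families, multi-species
contamination, and abundance biases of real libraries. Passing recovery
tests therefore demonstrates that the statistics and the decision cascade
are implemented correctly and are mutually consistent with the generative
models — not that the thresholds are optimal for any particular real
dataset.

# Mapping

Reads are length-filtered to 17–40 nt and aligned without gaps — indels are
never allowed, matching an alignment policy whose gap costs are effectively
infinite. Three modes:

* `end_to_end`: every offset on either strand where the whole read matches
  with at most `max_mismatch` (default 2) mismatches. Any `N` is a mismatch.
* `exact`: the same with zero mismatches.
* `local`: the single best ungapped placement allowing soft-clipped read
  ends; the aligned core must be ≥ 15 nt with at most `max_mismatch`
  mismatches. "Best" is the longest core, then fewest mismatches, then the
  smallest start, then `+` before `−`. The 15 nt core floor is this
  package's choice: seeded local modes of production aligners have no exact
  ungapped equivalent.

Base qualities are ignored (synthetic reads have uniform quality), a
documented deviation from quality-aware mismatch counting. Coordinates are
0-based half-open on the forward strand; `−` strand alignments report
forward-strand intervals while `five_prime_base` reports the first base of
the read as sequenced (T shown as U). `hierarchical_map()` assigns each read
to the first reference set (e.g. rRNA+miRNA before virus/COI/TE) with any
alignment — `first_hit` keeps the single best alignment, `all_hits` keeps
every placement, and profiling counts alignments, not fractionally weighted
reads.

The mapper is brute force (with early termination) in C++, checked in the
test suite against an independent exhaustive Hamming-scan oracle written in
plain R; at the desk scales used here (≤ 2 kb contigs, 10⁴–10⁵ reads) an
FM-index would be needless complexity.

# Per-contig statistics

* **Size profile**: alignment counts over length × strand × 5'-base; modal
  length per strand (ties broken toward the smaller length, for
  determinism) and per-strand 5'U fraction derive from it.
* **Coverage**: counts of 5' ends per position and strand (`start` for `+`,
  `end − 1` for `−`).
* **Sequence logo**: unique sequences of the modal length on one strand;
  per-position information content `IC = 2 + Σ f log₂ f` bits with no
  small-sample correction, letter heights `f × IC`. Deduplication to unique
  sequences (for logos and position-10 A) removes abundance weighting;
  size profiles and coverage deliberately keep it.
* **Ping-pong**: for every opposite-strand pair on a contig the 5'-to-5'
  overlap is the span between facing 5' ends, `o = e − s + 1`, histogrammed
  over 1–30. The `z10` score compares the o = 10 count with the mean and SD
  of the counts at o ∈ {1..30} \ {8..12}; the exclusion window keeps
  shoulder pairs out of the null. The overlap is *not* capped at the read
  length: capping makes every bin beyond the typical read length
  structurally empty and biases z10 upward under a strand-symmetric null,
  whereas the uncapped span gives a flat null histogram (the package's
  tests verify a mean null z10 within ±0.5). z10 is reported absent when
  there are no pairs or the background SD is zero.
* **Strand bias**: the positive-sense fraction of stranded RNA-seq counts
  with a binomial likelihood-ratio interval — endpoints of
  `{p : 2[ℓ(p̂) − ℓ(p)] ≤ χ²₁(conf)}` located by bisection to 1e-9.
* **Oxidation enrichment**: `(class_ox/anchor_ox)/(class_unt/anchor_unt)`
  with miRNA-mapped counts as the anchor; a fully methylated class
  converges to `1/f_ox` in expectation.

# Classification

`classify_contig()` applies a fixed cascade to eligible contigs (longer than
750 bp with at least 20 mapped small RNAs — the same inclusion rule used for
the quadrant scatter it numericises). With `x` the 20–31 nt sRNA : RNA-seq
ratio and `y` the 20–24 : 25–31 nt ratio:

1. `viRNA_like` — `y > 1` (or undefined because no 25–31 nt reads exist),
   modal length 20–24 nt, `x ≥ 0.01`;
2. `piRNA_pingpong` — `z10 ≥ 3` and position-10 A fraction ≥ 0.5 on the
   better strand;
3. `piRNA_primary` — modal length 25–31 nt and a strand with 5'U ≥ 0.75;
4. `unbiased_26_30` — modal length 25–31 nt and `x ≥ 0.01` with neither
   bias (the whelk-type signature);
5. `degradation_or_none` otherwise.

The quadrant boundaries (`y = 1`, `x = 0.01`), the 0.75 5'U cut
(operationalising "almost exclusively 5'U"), and the ping-pong thresholds
(`z10 ≥ 3`, A10 ≥ 0.5) are this package's choices — the source analyses
present log-scale scatters and logos without numeric boundaries — and all
live in `classification_thresholds()`. Labels are mutually exclusive by
construction; mixed or intermediate signatures fall to the first matching
rule, and the full `signature_report()` row retains every raw statistic so
mixtures stay visible.

Replication/EVE assessment uses the strand-bias interval: a −ssRNA virus is
`replicating` when the lower bound of the positive fraction exceeds 0 (its
genome alone cannot produce positive-sense reads), dsRNA when it exceeds
0.5, +ssRNA when the upper bound is below 1 (a conservative test — positive
to negative strand ratios of replicating +ssRNA viruses can reach 1000:1,
so absence of negative-sense reads is not evidence of absence), and an
ssDNA contig with an upper bound below 0.5 is a `putative_EVE` (host-driven
antisense expression of an integrated copy rather than mRNA expression).

# Pooled prevalence

A pool of `n` individuals assays positive unless all members are
uninfected: `P(+) = 1 − (1−p)^n`, assuming independent pools and perfect
assay sensitivity/specificity (a single successful amplification marks a
pool positive). `estimate_prevalence()` maximises the resulting
log-likelihood over [0, 1] (`stats::optimize`, tolerance 1e-9) and reports
the 2-log-likelihood support interval `{p : logL(p) ≥ max − 2}` — the
standard support-interval reading of a "2 log-likelihood interval", about a
95.4% confidence interval asymptotically — with endpoints by bisection.
All-negative surveys give exactly 0 (lower bound 0); all-positive give 1
(upper bound 1). `ubiquity_threshold()` inverts the design: the minimal
prevalence at which every pool is positive with probability α, i.e. the
prevalence above which a virus is indistinguishable from fixed — relevant
because apparent ubiquity in pooled surveys is weak evidence for genomic
integration when pools are large.

```{r prevalence-example}
fit <- estimate_prevalence(
  tibble::tibble(pool_size = rep(30, 4),
                 positive = c(TRUE, FALSE, FALSE, FALSE)))
tidy(fit)
ubiquity_threshold(c(10, 10, 10, 7), alpha = 0.95)
```

# A worked synthetic run

```{r benchmark}
bench <- sim_benchmark(seed = 7, n_reads = 2000)
aln <- map_reads(bench$reads, bench$contigs)
report <- signature_report(aln, bench$contigs, bench$rnaseq)
report |>
  select(contig_id, n_srna, modal_length_pos, modal_length_neg,
         z10, pos10_A_max, x_ratio, y_ratio, label) |>
  left_join(bench$truth, by = "contig_id")
```

```{r plots, fig.width = 6, fig.height = 3}
pp_contig <- bench$contigs$contig_id[3]
pp_aln <- dplyr::filter(aln, contig_id == pp_contig)
plot_size_profile(size_profile(pp_aln))
autoplot(ping_pong_signature(pp_aln))
```

# Problem sizes and determinism

Every stochastic function takes an explicit seed, and seeded runs are
bit-reproducible; `run_pipeline()` records the seed and thresholds in its
JSON run summary, and identical inputs give byte-identical outputs. The
validation suite works at desk scale, chosen to estimate each property
stably: mapper-vs-oracle checks use 50 random instances of ≤ 2 kb contigs
with 500 reads each; generator-recovery uses five 2 kb contigs × 2000 reads
over 20 seeds; ping-pong null calibration uses 200 replicates of 250
strand-symmetric reads; interval calibrations use 1000–2000 simulated
replicates.

# Known limitations

* Thresholds were chosen to separate the generator's well-separated default
  classes; real contigs with mixed targeting (e.g. a TE processed by both a
  piRNA and an siRNA pathway, or weak-5'U intermediates) receive the first
  matching label, and only the raw statistics reveal the mixture. No
  dedicated "intermediate" class is defined.
* Multi-mapping reads are counted once per alignment; with families of
  near-identical contigs this inflates per-contig counts.
* The mapper ignores base quality and never aligns across indels, so a
  genuinely edited read with an insertion is lost in all modes.
* The prevalence model has no assay-error term; imperfect PCR sensitivity
  biases prevalence downward.
* z10 is a pragmatic detection statistic, not a calibrated p-value; its
  null spread depends on hotspot structure, which is why classification
  also requires the position-10 A mark.
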