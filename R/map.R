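#' Length-filter small-RNA reads
#'
#' Retains reads whose length lies in `[min_len, max_len]` (defaults 17--40
#' nt, the adapter-trimmed window used throughout), preserving input order.
#'
#' @param reads Read tibble with a `seq` column.
#' @param min_len,max_len Inclusive length bounds in nt.
#' @return The filtered tibble.
#' @export
filter_read_length <- function(reads, min_len = 17L, max_len = 40L) {
  if (min_len > max_len) {
    stop("`min_len` must be <= `max_len`", call. = FALSE)
  }
  len <- nchar(reads$seq)
  reads[len >= min_len & len <= max_len, , drop = FALSE]
}

empty_alignments <- function() {
  tibble::tibble(read_id = character(0), contig_id = character(0),
                 start = integer(0), end = integer(0), strand = character(0),
                 mismatches = integer(0), read_length = integer(0),
                 five_prime_base = character(0), seq = character(0))
}

#' Map reads to contigs, ungapped
#'
#' Aligns each read to each contig without gaps, on both strands.
#'
#' * `end_to_end`: every offset where the whole read matches with at most
#'   `max_mismatch` mismatches (the read is reverse-complemented for the
#'   `-` strand).
#' * `exact`: `end_to_end` with `max_mismatch` forced to 0.
#' * `local`: the single best ungapped placement per read/contig, allowing
#'   soft-clipped read ends; the aligned core must be at least `min_core` nt
#'   with at most `max_mismatch` mismatches. Best means longest core, then
#'   fewest mismatches, then smallest start, then `+` before `-`.
#'
#' Indels are never allowed, and any `N` counts as a mismatch. Coordinates
#' are 0-based half-open on the contig forward strand; `-` strand alignments
#' report forward-strand intervals, but `five_prime_base` is the first base
#' of the read as sequenced (T reported as U). Results are sorted by read,
#' then (mismatches, start, `+` before `-`).
#'
#' @param reads Read tibble (`read_id`, `seq`).
#' @param contigs Contig tibble (`contig_id`, `sequence`).
#' @param mode Alignment mode.
#' @param max_mismatch Mismatch budget (default 2).
#' @param min_core Minimum aligned core length for `local` mode.
#' @return An alignment tibble with columns `read_id`, `contig_id`, `start`,
#'   `end`, `strand`, `mismatches`, `read_length`, `five_prime_base`, `seq`.
#'   In `local` mode `start`/`end` delimit the aligned core.
#' @export
map_reads <- function(reads, contigs,
                      mode = c("end_to_end", "local", "exact"),
                      max_mismatch = 2L, min_core = 15L) {
  mode <- match.arg(mode)
  stopifnot_count(max_mismatch, "max_mismatch")
  if (mode == "exact") max_mismatch <- 0L
  n_reads <- nrow(reads)
  if (n_reads == 0L || nrow(contigs) == 0L) return(empty_alignments())
  rc <- revcomp(reads$seq)
  rlen <- nchar(reads$seq)
  per_contig <- vector("list", nrow(contigs))
  for (ci in seq_len(nrow(contigs))) {
    cseq <- contigs$sequence[[ci]]
    if (mode == "local") {
      h <- scan_batch_local_cpp(reads$seq, rc, cseq, max_mismatch, min_core)
      if (!length(h$read)) next
      per_contig[[ci]] <- list(ri = h$read, ci = rep.int(ci, length(h$read)),
                               start = h$start, end = h$start + h$core_len,
                               strand = h$strand, mm = h$mismatches)
    } else {
      h <- scan_batch_e2e_cpp(reads$seq, rc, cseq, max_mismatch)
      if (!length(h$read)) next
      per_contig[[ci]] <- list(ri = h$read, ci = rep.int(ci, length(h$read)),
                               start = h$start,
                               end = h$start + rlen[h$read],
                               strand = h$strand, mm = h$mismatches)
    }
  }
  per_contig <- per_contig[!vapply(per_contig, is.null, logical(1))]
  if (!length(per_contig)) return(empty_alignments())
  pull <- function(f) unlist(lapply(per_contig, `[[`, f), use.names = FALSE)
  ri <- pull("ri")
  out <- tibble::tibble(
    read_id = reads$read_id[ri],
    contig_id = contigs$contig_id[pull("ci")],
    start = pull("start"),
    end = pull("end"),
    strand = c("+", "-")[pull("strand") + 1L],
    mismatches = pull("mm"),
    read_length = rlen[ri],
    five_prime_base = five_prime_base(reads$seq[ri]),
    seq = reads$seq[ri]
  )
  ord <- order(out$read_id, out$contig_id, out$mismatches, out$start,
               out$strand == "-")
  out[ord, , drop = FALSE]
}

#' Hierarchically assign reads across ordered reference sets
#'
#' Reproduces hierarchical mapping: each read is assigned to the first
#' reference set in which it has any alignment; only reads left unmapped by a
#' set are offered to the next. A set's `policy` is either `"first_hit"`
#' (keep the single best alignment: fewest mismatches, then contig order,
#' then start, then `+` before `-`) or `"all_hits"` (keep every alignment).
#'
#' @param reads Read tibble.
#' @param reference_sets Ordered list; each element is a list with `name`
#'   (unique), `contigs` (contig tibble) and optional `policy`
#'   (default `"all_hits"`).
#' @param mode,max_mismatch Passed to [map_reads()].
#' @return An alignment tibble with an extra `set` column, carrying the ids
#'   of reads matching no set in `attr(, "unmapped")` (see
#'   [unmapped_reads()]).
#' @export
hierarchical_map <- function(reads, reference_sets,
                             mode = "end_to_end", max_mismatch = 2L) {
  nms <- vapply(reference_sets, function(x) x$name, character(1))
  if (anyDuplicated(nms)) {
    stop("reference-set names must be unique", call. = FALSE)
  }
  remaining <- reads
  out <- list()
  for (rs in reference_sets) {
    if (nrow(remaining) == 0L) break
    aln <- map_reads(remaining, rs$contigs, mode = mode,
                     max_mismatch = max_mismatch)
    if (nrow(aln) == 0L) next
    policy <- rs$policy %||% "all_hits"
    if (policy == "first_hit") {
      contig_rank <- match(aln$contig_id, rs$contigs$contig_id)
      aln <- aln[order(aln$read_id, aln$mismatches, contig_rank, aln$start,
                       factor(aln$strand, levels = c("+", "-"))), ]
      aln <- aln[!duplicated(aln$read_id), , drop = FALSE]
    } else if (policy != "all_hits") {
      stop(sprintf("unknown policy '%s'", policy), call. = FALSE)
    }
    aln$set <- rs$name
    out[[rs$name]] <- aln
    remaining <- remaining[!remaining$read_id %in% aln$read_id, ,
                           drop = FALSE]
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    dplyr::mutate(empty_alignments(), set = character(0))
  res <- dplyr::relocate(res, "set", .after = "read_id")
  attr(res, "unmapped") <- remaining$read_id
  res
}

#' Ids of reads left unassigned by [hierarchical_map()]
#' @param alignments Result of [hierarchical_map()].
#' @return Character vector of read ids.
#' @export
unmapped_reads <- function(alignments) {
  attr(alignments, "unmapped") %||% character(0)
}
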