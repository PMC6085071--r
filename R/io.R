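#' Load contigs from FASTA
#'
#' @param path FASTA file.
#' @param metadata Optional tibble/TSV path with `contig_id`, `category`,
#'   `genome_type` to join on.
#' @return A contig tibble (`contig_id`, `sequence`, `length`, and metadata
#'   columns when supplied).
#' @export
load_contigs <- function(path, metadata = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("contig FASTA not found: %s", path), call. = FALSE)
  }
  ss <- Biostrings::readDNAStringSet(path)
  out <- tibble::tibble(
    contig_id = sub("\\s.*$", "", names(ss)),
    sequence = unname(toupper(as.character(ss))),
    length = Biostrings::width(ss)
  )
  if (!is.null(metadata)) {
    if (is.character(metadata)) {
      metadata <- readr::read_tsv(metadata, show_col_types = FALSE)
    }
    out <- dplyr::left_join(out, metadata, by = "contig_id")
  }
  out
}

#' Load small-RNA reads from FASTA or FASTQ
#'
#' Sequences are uppercased and stored in the DNA alphabet; the RNA (T as U)
#' convention is applied only in reporting columns downstream.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @param library_id Library label attached to every read.
#' @return A read tibble (`read_id`, `seq`, `library_id`). An empty file
#'   yields an empty tibble with a warning.
#' @export
load_small_reads <- function(path, format = c("auto", "fasta", "fastq"),
                             library_id = "lib1") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("read file not found: %s", path), call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  ss <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e) {
      stop(sprintf("failed to parse %s as %s: %s", path, format,
                   conditionMessage(e)), call. = FALSE)
    })
  if (length(ss) == 0L) {
    warning(sprintf("no records in %s", path), call. = FALSE)
  }
  tibble::tibble(
    read_id = sub("\\s.*$", "", names(ss)),
    seq = unname(toupper(as.character(ss))),
    library_id = library_id
  )
}

#' Write contigs to FASTA
#' @param contigs Contig tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_contigs_fasta <- function(contigs, path) {
  ss <- Biostrings::DNAStringSet(contigs$sequence)
  names(ss) <- contigs$contig_id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write reads to FASTQ (uniform quality "I") or FASTA
#' @param reads Read tibble.
#' @param path Output file.
#' @param format `"fastq"` or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- reads$read_id
  if (format == "fastq") {
    quals <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
    Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = quals)
  } else {
    Biostrings::writeXStringSet(ss, path)
  }
  invisible(path)
}

#' Write the truth sidecar for simulated reads
#'
#' Records the truth-only fields (class, source contig/strand, biochemical
#' flags) as TSV so generated datasets stay verifiable after round-tripping
#' through FASTQ.
#'
#' @param reads Read tibble from [sim_small_reads()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_truth_sidecar <- function(reads, path) {
  readr::write_tsv(
    dplyr::select(reads, "read_id", "truth_class", "source_contig",
                  "source_strand", "has_5p_triphosphate", "has_3p_2ome"),
    path)
  invisible(path)
}
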