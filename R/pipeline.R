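#' Run the full signature pipeline
#'
#' Orchestrates length filtering, hierarchical mapping, per-contig profiling
#' and classification, and (when a pooled survey is supplied) prevalence
#' estimation, writing all outputs as TSV/JSON under `out_dir`. With
#' identical inputs and seed the output files are byte-identical.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   * `contigs`: path to the contig FASTA.
#'   * `contig_metadata`: optional TSV with `contig_id`, `category`,
#'     `genome_type`.
#'   * `reads`: named list of read files (names become library ids), or a
#'     single path.
#'   * `rnaseq_counts`: optional TSV with `contig_id`, `pos_count`,
#'     `neg_count`.
#'   * `pool_survey`: optional TSV with `virus_id`, `pool_size`, `positive`.
#'   * `mapping`: optional list with `mode`, `max_mismatch`,
#'     `reference_sets` (list of `name`, `categories`, `policy`; categories
#'     select contigs by their `category` column). Defaults to one
#'     `all_hits` set holding every contig.
#'   * `thresholds`: optional overrides for [classification_thresholds()].
#'   * `min_len`, `max_len`: read length filter (defaults 17, 40).
#'   * `seed`: integer recorded in the run summary.
#'   * `out_dir`: output directory (created if missing).
#' @return Invisibly, a list with `alignments`, `report`, `prevalence` (or
#'   `NULL`) and the path of each written file.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop("config$out_dir is required",
                                      call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L

  contigs <- load_contigs(config$contigs, config$contig_metadata)
  read_paths <- config$reads
  if (is.character(read_paths) && is.null(names(read_paths))) {
    read_paths <- stats::setNames(as.list(read_paths),
                                  paste0("lib", seq_along(read_paths)))
  }
  reads <- dplyr::bind_rows(purrr::imap(
    read_paths, function(p, nm) load_small_reads(p, library_id = nm)))
  reads <- filter_read_length(reads, config$min_len %||% 17L,
                              config$max_len %||% 40L)

  mapping <- config$mapping %||% list()
  ref_cfg <- mapping$reference_sets %||%
    list(list(name = "all", categories = NULL, policy = "all_hits"))
  reference_sets <- purrr::map(ref_cfg, function(rs) {
    sel <- if (is.null(rs$categories) || !"category" %in% names(contigs)) {
      contigs
    } else {
      contigs[contigs$category %in% rs$categories, , drop = FALSE]
    }
    list(name = rs$name, contigs = sel, policy = rs$policy %||% "all_hits")
  })
  alignments <- hierarchical_map(reads, reference_sets,
                                 mode = mapping$mode %||% "end_to_end",
                                 max_mismatch = mapping$max_mismatch %||% 2L)

  rnaseq <- NULL
  if (!is.null(config$rnaseq_counts)) {
    rnaseq <- readr::read_tsv(config$rnaseq_counts, show_col_types = FALSE)
  }
  thresholds <- do.call(classification_thresholds,
                        config$thresholds %||% list())
  report <- signature_report(alignments, contigs, rnaseq,
                             thresholds = thresholds)

  profiles <- alignments |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::group_modify(function(df, key) size_profile(df)) |>
    dplyr::ungroup()
  coverage <- purrr::map_dfr(unique(alignments$contig_id), function(cid) {
    clen <- contigs$length[contigs$contig_id == cid][[1]]
    cov <- positional_coverage(
      alignments[alignments$contig_id == cid, , drop = FALSE], clen)
    dplyr::mutate(cov, contig_id = cid, .before = 1L)
  })

  prevalence <- NULL
  if (!is.null(config$pool_survey)) {
    survey <- readr::read_tsv(config$pool_survey, show_col_types = FALSE)
    prevalence <- survey |>
      dplyr::group_by(.data$virus_id) |>
      dplyr::group_modify(function(df, key) {
        fit <- estimate_prevalence(df)
        tibble::tibble(p_hat = fit$p_hat, lower = fit$lower,
                       upper = fit$upper, percent = 100 * fit$p_hat,
                       n_pools = fit$n_pools,
                       n_individuals = fit$n_individuals)
      }) |>
      dplyr::ungroup()
  }

  paths <- list(
    alignments = file.path(out_dir, "alignments.tsv"),
    profiles = file.path(out_dir, "size_profiles.tsv"),
    coverage = file.path(out_dir, "coverage.tsv"),
    report = file.path(out_dir, "signature_report.tsv"),
    summary = file.path(out_dir, "run_summary.json")
  )
  readr::write_tsv(dplyr::select(alignments, -"seq"), paths$alignments)
  readr::write_tsv(profiles, paths$profiles)
  readr::write_tsv(coverage, paths$coverage)
  readr::write_tsv(report, paths$report)
  if (!is.null(prevalence)) {
    paths$prevalence <- file.path(out_dir, "prevalence.tsv")
    readr::write_tsv(prevalence, paths$prevalence)
  }
  summary <- list(
    seed = seed,
    n_reads = nrow(reads),
    n_contigs = nrow(contigs),
    n_alignments = nrow(alignments),
    n_unmapped = length(unmapped_reads(alignments)),
    mapping = list(mode = mapping$mode %||% "end_to_end",
                   max_mismatch = mapping$max_mismatch %||% 2L,
                   reference_sets = purrr::map_chr(reference_sets, "name")),
    thresholds = thresholds,
    labels = as.list(table(report$label))
  )
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(alignments = alignments, report = report,
                 prevalence = prevalence, paths = paths))
}
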