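BASE_COLOURS <- c(U = "#d7191c", G = "#fdae61", C = "#2c7bb6", A = "#1a9641")

#' Plot a size x 5'-base profile
#'
#' Stacked bars of alignment counts by read length, coloured by 5' base,
#' with positive-strand counts above and negative-strand counts below the
#' x-axis -- the standard small-RNA size-distribution panel.
#'
#' @param profile A [size_profile()] tibble.
#' @return A ggplot object.
#' @export
plot_size_profile <- function(profile) {
  df <- dplyr::mutate(
    profile,
    signed_n = ifelse(.data$strand == "+", .data$n, -.data$n),
    base = factor(.data$base, levels = names(BASE_COLOURS)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, y = .data$signed_n,
                                   fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = BASE_COLOURS, name = "5' base") +
    ggplot2::labs(x = "read length (nt)",
                  y = "alignments (+ above, - below)") +
    ggplot2::theme_minimal()
}

#' Plot 5'-end coverage along a contig
#'
#' @param coverage A [positional_coverage()] tibble.
#' @return A ggplot object.
#' @export
plot_coverage <- function(coverage) {
  ggplot2::ggplot(coverage) +
    ggplot2::geom_col(ggplot2::aes(x = .data$position, y = .data$pos_starts),
                      fill = "#d7191c", width = 1) +
    ggplot2::geom_col(ggplot2::aes(x = .data$position,
                                   y = -.data$neg_starts),
                      fill = "#2c7bb6", width = 1) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "contig position (bp)",
                  y = "5' ends (+ above, - below)") +
    ggplot2::theme_minimal()
}

#' Plot a sequence logo
#'
#' Letter heights are base frequency times per-position information content
#' (bits, 0--2).
#'
#' @param logo A [sequence_logo()] tibble.
#' @return A ggplot object.
#' @export
plot_logo <- function(logo) {
  df <- logo[logo$height > 0, , drop = FALSE] |>
    dplyr::arrange(.data$position, .data$height) |>
    dplyr::mutate(ymax = cumsum(.data$height),
                  ymin = .data$ymax - .data$height,
                  .by = "position")
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$position - 0.45,
                                    xmax = .data$position + 0.45,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$base),
                       colour = "white", linewidth = 0.2) +
    ggplot2::geom_text(ggplot2::aes(
      x = .data$position, y = (.data$ymin + .data$ymax) / 2,
      label = .data$base), colour = "white", size = 2.5) +
    ggplot2::scale_fill_manual(values = BASE_COLOURS, guide = "none") +
    ggplot2::labs(x = "read position", y = "information (bits)") +
    ggplot2::ylim(0, 2) +
    ggplot2::theme_minimal()
}

#' @describeIn ping_pong_signature Histogram of 5'-to-5' overlap counts with
#'   the o = 10 ping-pong bin highlighted.
#' @param object A `pingpong_result`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.pingpong_result <- function(object, ...) {
  df <- dplyr::mutate(object$overlap_histogram,
                      pingpong = .data$overlap == 10L)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$overlap, y = .data$n_pairs,
                                   fill = .data$pingpong)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#d7191c",
                                          `FALSE` = "grey60"),
                               guide = "none") +
    ggplot2::labs(x = "5'-to-5' overlap (nt)", y = "read pairs",
                  subtitle = sprintf("z10 = %s",
                                     format(object$z10, digits = 3))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
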