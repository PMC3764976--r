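#' Plot a saturation curve
#'
#' Detected reference sequences (per hit threshold) against the number of
#' sampled reads.
#'
#' @param object An `hx_saturation` tibble from [saturation_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hx_saturation <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    dplyr::starts_with("refs_ge"),
    names_to = "threshold", values_to = "n_refs",
    names_prefix = "refs_ge"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$n_reads, .data$n_refs,
                                     colour = .data$threshold)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "sampled reads", y = "reference sequences detected",
      colour = "reads mapped ≥"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an ORF coverage profile
#'
#' @param object An `hx_orf_profile` from [coverage_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hx_orf_profile <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(.data$bin_low + (.data$bin_high -
                                                  .data$bin_low) / 2,
                               .data$count)) +
    ggplot2::geom_col(width = object$histogram$bin_high[[1]] -
                        object$histogram$bin_low[[1]]) +
    ggplot2::labs(x = "fraction of transcript covered by the ORF",
                  y = "transcripts") +
    ggplot2::theme_minimal()
}

#' Plot the length distribution of a sequence set
#'
#' @param records A [seq_tbl()].
#' @param binwidth Histogram bin width (nt).
#' @return A ggplot.
#' @export
plot_length_dist <- function(records, binwidth = 50) {
  ggplot2::ggplot(tibble::tibble(length = nchar(records$seq)),
                  ggplot2::aes(.data$length)) +
    ggplot2::geom_histogram(binwidth = binwidth) +
    ggplot2::labs(x = "sequence length (nt)", y = "records") +
    ggplot2::theme_minimal()
}

#' Plot coding-length comparison classes
#'
#' @param object An `hx_length_compare` from [coding_length_compare()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hx_length_compare <- function(object, ...) {
  ggplot2::ggplot(object$per_reference, ggplot2::aes(.data$class)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "hit length relative to reference", y = "references") +
    ggplot2::theme_minimal()
}
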