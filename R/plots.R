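#' Plot an enrichment result
#'
#' Histogram of the MAF-matched null counts with the observed count as a
#' vertical line; an observed line far to the right of the null mass is the
#' visual signature of enrichment.
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- tibble::tibble(null_count = object$null_counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_count)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(
      xintercept = object$observed, colour = "black", linewidth = 1
    ) +
    ggplot2::labs(
      x = sprintf("%s count per MAF-matched replicate", object$statistic),
      y = "replicates",
      title = sprintf(
        "Observed %.0f vs %d null replicates (empirical p %s)",
        object$observed, object$n_reps,
        if (object$empirical_p == 0) {
          sprintf("< %s", format(1 / object$n_reps))
        } else {
          format(object$empirical_p)
        }
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a bin series
#'
#' Per-bin observed counts (points) against the flat expectation (solid
#' line) and the simulated 95% bands (dotted lines), the standard display
#' for score-ordered and association-ordered prioritization series.
#'
#' @param object A `bin_series`.
#' @param max_bins Show at most this many leading bins (default all); the
#'   informative signal concentrates in the first bins, so display is often
#'   truncated.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bin_series
#' @export
autoplot.bin_series <- function(object, max_bins = Inf, ...) {
  df <- utils::head(object$series, max_bins)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin + 1)) +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$band_low),
      linetype = "dotted", colour = "grey40"
    ) +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$band_high),
      linetype = "dotted", colour = "grey40"
    ) +
    ggplot2::geom_hline(
      yintercept = sum(object$series$count) / sum(object$series$n) *
        object$bin_size, colour = "grey30"
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$count)) +
    ggplot2::labs(
      x = sprintf(
        "bin of %d SNPs (%s)", object$bin_size,
        if (object$ordering == "by_score_desc") {
          "highest eQTL function score first"
        } else {
          "smallest association p first"
        }
      ),
      y = switch(object$threshold_kind,
        assoc = sprintf("SNPs with association p < %s", format(object$threshold)),
        score = sprintf("SNPs with score > %s", format(object$threshold))
      )
    ) +
    ggplot2::theme_minimal()
}
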