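#' Methods for experiment reports
#'
#' `tidy()` returns the per-read-length Spearman statistics, `glance()` a
#' one-row summary of the whole experiment, and `autoplot()` the
#' distance-binned BPS boxplot (the diagnostic view of the core claim:
#' BPS should fall as the Levenshtein distance grows).
#'
#' @name report_methods
NULL

#' @rdname report_methods
#' @param x A `bps_experiment` from [run_experiment()].
#' @param ... Unused.
#' @method tidy bps_experiment
#' @export
tidy.bps_experiment <- function(x, ...) {
  x$stats$per_length_spearman
}

#' @rdname report_methods
#' @method glance bps_experiment
#' @export
glance.bps_experiment <- function(x, ...) {
  tibble::tibble(
    n_records = nrow(x$records),
    n_sequences = length(unique(x$records$sequence_id)),
    n_failures = nrow(x$failures),
    spearman_rho = x$stats$pooled_spearman$rho,
    spearman_p = x$stats$pooled_spearman$p_value,
    anova_F = x$stats$anova$F_statistic,
    anova_p = x$stats$anova$p_value,
    median_levenshtein = stats::median(x$records$levenshtein)
  )
}

#' @rdname report_methods
#' @param object A `bps_experiment`.
#' @param bps_field Score variant to plot (default `"bps"`).
#' @method autoplot bps_experiment
#' @export
autoplot.bps_experiment <- function(object, bps_field = "bps", ...) {
  bw <- object$stats$bin_width
  d <- object$records
  d$bin <- floor(d$levenshtein / bw) * bw
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$bin),
                                  y = .data[[bps_field]])) +
    ggplot2::geom_boxplot(outlier.size = 0.5, fill = "grey85") +
    ggplot2::facet_wrap(~read_length, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = sprintf("Levenshtein distance to truth (bin width %d)", bw),
      y = bps_field,
      title = "Breakage propensity score vs assembly quality") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname report_methods
#' @export
print.bps_experiment <- function(x, ...) {
  g <- glance(x)
  cat("<bps_experiment>\n")
  cat(sprintf("  %d evaluation records from %d reference(s); %d failed unit(s)\n",
              g$n_records, g$n_sequences, g$n_failures))
  cat(sprintf("  pooled Spearman rho (bps vs similarity): %.3f (p = %.3g)\n",
              g$spearman_rho, g$spearman_p))
  cat(sprintf("  ANOVA across distance bins: F = %.2f (p = %.3g)\n",
              g$anova_F, g$anova_p))
  cat(sprintf("  median Levenshtein distance: %g\n", g$median_levenshtein))
  invisible(x)
}
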