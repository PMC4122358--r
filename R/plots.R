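# ggplot2 graphics for the main result surfaces.

#' Plot the four-class frequencies of one or more comparisons
#'
#' Bar chart of N/P, N/N, P/N, P/P percentages, the per-comparison view of
#' the concomitant-change analysis.
#'
#' @param counts A `class_counts` object, or a tibble binding several
#'   tidied ones (columns `class`, `pct`, `comparison`).
#' @return A ggplot object.
#' @export
plot_class_frequencies <- function(counts) {
  df <- if (inherits(counts, "class_counts")) tidy(counts) else as_tibble(counts)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$pct,
                                        fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "sign class (delta bpi / delta GCi)", y = "% of pairs") +
    ggplot2::theme_minimal()
  if (!all(is.na(df$comparison))) {
    p <- p + ggplot2::facet_wrap(~comparison)
  }
  p
}

#' @method autoplot class_counts
#' @export
autoplot.class_counts <- function(object, ...) plot_class_frequencies(object)

#' Histogram of an intronic GC distribution
#'
#' GCi histogram for one species with the mean and skewness annotated.
#'
#' @param ds A [species_dataset()].
#' @param binwidth Histogram bin width in GC points.
#' @return A ggplot object.
#' @export
plot_gci_distribution <- function(ds, binwidth = 2) {
  stopifnot(inherits(ds, "species_dataset"))
  intr <- ds$introns[ds$introns$bpi > 0, ]
  lab <- sprintf("%s  mean GCi %.1f  SK %.2f", ds$species_id,
                 mean(intr$gci), skewness(intr$gci))
  ggplot2::ggplot(intr, ggplot2::aes(x = .data$gci)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey35") +
    ggplot2::labs(title = lab, x = "GCi (%)", y = "genes") +
    ggplot2::theme_minimal()
}

#' Plot a respirometry trace and its fitted depletion line
#'
#' @param x A [respirometry_trace()].
#' @param fit Optional `o2_fit` for the trace; computed if omitted.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot respirometry_trace
#' @export
autoplot.respirometry_trace <- function(x, fit = NULL, ...) {
  fit <- fit %||% consumption_rate(x)
  ggplot2::ggplot(as_tibble(x), ggplot2::aes(x = .data$time_h, y = .data$o2_ug)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_abline(intercept = coef(fit$fit)[1], slope = coef(fit$fit)[2],
                         colour = "firebrick") +
    ggplot2::labs(x = "time (h)", y = "chamber O2 (ug)",
                  title = sprintf("%.3g ugO2/h, R^2 %.3f",
                                  fit$rate_ug_h, fit$r_squared)) +
    ggplot2::theme_minimal()
}

#' Box plots of temperature-corrected metabolic rate per species
#'
#' @param records Per-specimen MR records from [summarize_mr()].
#' @param log_scale Plot the log-normalised values.
#' @return A ggplot object.
#' @export
plot_mr <- function(records, log_scale = TRUE) {
  y <- if (log_scale) "log_mr" else "mr"
  ggplot2::ggplot(records, ggplot2::aes(x = .data$species_id,
                                        y = .data[[y]])) +
    ggplot2::geom_boxplot(fill = "grey80") +
    ggplot2::labs(x = NULL,
                  y = if (log_scale) "log MR" else "MR (mgO2/kg/h)") +
    ggplot2::theme_minimal()
}
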