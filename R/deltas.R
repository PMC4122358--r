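# Per-pair differences of intronic length and GC content, the negligible-
# difference filter, percent-positive statistics, the four sign classes
# (N/P, N/N, P/N, P/P) and their exact binomial significance.

DELTA_CLASSES <- c("N/P", "N/N", "P/N", "P/P")

#' Compute per-pair intron deltas
#'
#' For each ortholog intron pair, the signed differences
#' `delta_bpi = bpi_m - bpi_z` (bases) and `delta_gci = gci_m - gci_z`
#' (GC percentage points), oriented as first species minus second.
#'
#' @param intron_pairs Tibble from [extend_to_introns()] (columns `gene_m`,
#'   `gene_z`, `bpi_m`, `gci_m`, `bpi_z`, `gci_z`).
#' @param species Length-2 character vector naming the orientation
#'   `(m, z)`.
#' @param masked_variant `"before"` or `"after"` repeat masking; both
#'   members of every pair must have been measured under this variant.
#' @return Tibble of delta records: `gene_m`, `gene_z`, `delta_bpi`,
#'   `delta_gci`, `masked_variant`, with attribute `species`.
#' @export
compute_deltas <- function(intron_pairs, species = c("m", "z"),
                           masked_variant = c("before", "after")) {
  masked_variant <- arg_match(masked_variant)
  stopifnot(all(c("gene_m", "gene_z", "bpi_m", "gci_m", "bpi_z", "gci_z")
                %in% names(intron_pairs)))
  if (anyNA(intron_pairs$gci_m) || anyNA(intron_pairs$gci_z)) {
    abort("Deltas require both members measured (no NA GCi); drop intronless genes first.",
          class = "introdelta_usage_error")
  }
  out <- tibble(
    gene_m = intron_pairs$gene_m,
    gene_z = intron_pairs$gene_z,
    delta_bpi = intron_pairs$bpi_m - intron_pairs$bpi_z,
    delta_gci = intron_pairs$gci_m - intron_pairs$gci_z,
    masked_variant = masked_variant
  )
  attr(out, "species") <- species
  out
}

#' Filter out negligible deltas
#'
#' Pairs with `|delta_gci| < gc_threshold` (default 0.1 GC points) and/or
#' `|delta_bpi| < bp_threshold` (default 100 bases) are disregarded from
#' further analysis; the inequality is strict, so boundary values are
#' retained. `rule = "or"` (default) removes a record when either delta is
#' negligible; `rule = "and"` only when both are.
#'
#' @param records Delta-record tibble from [compute_deltas()].
#' @param gc_threshold,bp_threshold Positive removal thresholds.
#' @param rule `"or"` or `"and"`.
#' @return The retained records, with attributes `n_removed` and
#'   `removed_fraction` (percent removed, see [removed_fraction()]).
#' @export
filter_deltas <- function(records, gc_threshold = 0.1, bp_threshold = 100,
                          rule = c("or", "and")) {
  rule <- arg_match(rule)
  stopifnot(gc_threshold > 0, bp_threshold > 0)
  small_gc <- abs(records$delta_gci) < gc_threshold
  small_bp <- abs(records$delta_bpi) < bp_threshold
  remove <- if (rule == "or") small_gc | small_bp else small_gc & small_bp
  out <- records[!remove, ]
  attr(out, "species") <- attr(records, "species")
  attr(out, "n_removed") <- sum(remove)
  attr(out, "removed_fraction") <-
    if (nrow(records)) 100 * sum(remove) / nrow(records) else NA_real_
  out
}

#' @rdname filter_deltas
#' @param filtered Output of `filter_deltas()`.
#' @return `removed_fraction()`: percent of records removed by the filter.
#' @export
removed_fraction <- function(filtered) {
  rf <- attr(filtered, "removed_fraction")
  if (is.null(rf)) abort("Not a filter_deltas() result.")
  rf
}

#' Percent of positive deltas
#'
#' `100 * #(variable > 0) / n` over filtered records; the percent of
#' negative deltas is the complement to one hundred (no zeros survive the
#' filter).
#'
#' @param records Filtered delta records.
#' @param variable `"delta_gci"` or `"delta_bpi"`.
#' @return Percentage in `[0, 100]`.
#' @export
percent_positive <- function(records, variable = c("delta_gci", "delta_bpi")) {
  variable <- arg_match(variable)
  x <- records[[variable]]
  if (length(x) == 0L) {
    abort("percent_positive() is undefined on an empty record set.",
          class = "introdelta_undefined_value")
  }
  100 * sum(x > 0) / length(x)
}

#' Classify delta records into the four sign classes
#'
#' Each pair is labelled by the sign pair of `(delta_bpi, delta_gci)`:
#' `N/P` (shorter, GC-richer in the first species), `N/N`, `P/N`, `P/P`.
#' Records must have passed [filter_deltas()], so both components are
#' nonzero.
#'
#' @param records Filtered delta records.
#' @return The records with a `class` factor column (levels
#'   `N/P`, `N/N`, `P/N`, `P/P`).
#' @export
classify_deltas <- function(records) {
  if (any(records$delta_bpi == 0) || any(records$delta_gci == 0)) {
    abort("Zero delta components must not reach classification; run filter_deltas() first.",
          class = "introdelta_contract_violation")
  }
  lab <- paste0(ifelse(records$delta_bpi > 0, "P", "N"), "/",
                ifelse(records$delta_gci > 0, "P", "N"))
  records$class <- factor(lab, levels = DELTA_CLASSES)
  records
}

#' Class frequencies of a pairwise comparison
#'
#' Counts and percentages of the four sign classes for one pairwise genome
#' comparison.
#'
#' @param records Classified delta records (from [classify_deltas()]; an
#'   unclassified filtered table is classified on the fly).
#' @param comparison Optional comparison label.
#' @return A `class_counts` tibble: one row per class with `class`, `n`,
#'   `pct`; attributes `n_total` and `comparison`.
#' @export
class_frequencies <- function(records, comparison = NULL) {
  if (!"class" %in% names(records)) records <- classify_deltas(records)
  counts <- table(records$class)
  out <- tibble(
    class = factor(DELTA_CLASSES, levels = DELTA_CLASSES),
    n = as.integer(counts[DELTA_CLASSES]),
    pct = 100 * as.integer(counts[DELTA_CLASSES]) / nrow(records)
  )
  attr(out, "n_total") <- nrow(records)
  attr(out, "comparison") <- comparison
  class(out) <- c("class_counts", class(out))
  out
}

#' Exact one-sided binomial test for the dominant class
#'
#' Tests whether the most frequent class exceeds its null expectation by
#' the exact one-sided upper-tail probability `P(X >= k_top)` for
#' `X ~ Binomial(n_total, null_p)`, computed by exact summation of the
#' probability mass function (no normal approximation).
#'
#' Under the default `null = "uniform"` the null probability is 1/4 (the
#' four classes equiprobable). `null = "top2"` instead tests the top class
#' against the runner-up on their union with `null_p = 1/2`.
#'
#' @param counts A `class_counts` object from [class_frequencies()].
#' @param null_p Null success probability (in `(0, 1)`); ignored for
#'   `null = "top2"`.
#' @param null `"uniform"` or `"top2"`.
#' @return One-row tibble: `top_class`, `k`, `n`, `null_p`, `p_value`.
#' @export
binomial_test_top_class <- function(counts, null_p = 0.25,
                                    null = c("uniform", "top2")) {
  null <- arg_match(null)
  stopifnot(inherits(counts, "class_counts"))
  ord <- order(counts$n, decreasing = TRUE)
  top <- ord[1]
  if (null == "uniform") {
    k <- counts$n[top]
    n <- attr(counts, "n_total")
  } else {
    k <- counts$n[top]
    n <- counts$n[top] + counts$n[ord[2]]
    null_p <- 0.5
  }
  tibble(
    top_class = as.character(counts$class[top]),
    k = k, n = n, null_p = null_p,
    p_value = binom_upper_tail(k, n, null_p)
  )
}

#' Exact upper-tail binomial probability
#'
#' `P(X >= k)` for `X ~ Binomial(n, p)` by exact summation of the pmf.
#'
#' @param k Observed count (0..n).
#' @param n Number of trials (>= 1).
#' @param p Success probability in `(0, 1)`.
#' @return Tail probability.
#' @export
binom_upper_tail <- function(k, n, p) {
  if (p <= 0 || p >= 1) {
    abort("Null probability must lie strictly in (0, 1).",
          class = "introdelta_parameter_error")
  }
  stopifnot(n >= 1, k >= 0, k <= n)
  if (k == 0) return(1)
  min(1, sum(dbinom(k:n, n, p)))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment of a family of p-values; adjusted values are monotone
#' non-decreasing after sorting. The comparison-wide family is all
#' pairwise comparisons times masking variants.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
adjust_fdr <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  p.adjust(pvalues, method = "BH")
}

#' Per-comparison delta summary
#'
#' The headline quantities of one pairwise comparison: ortholog count,
#' percent-positive deltas and mean deltas.
#'
#' @param records Filtered delta records.
#' @param comparison Optional label.
#' @return One-row tibble: `comparison`, `n`, `pct_positive_gci`,
#'   `pct_positive_bpi`, `mean_delta_gci`, `mean_delta_bpi`.
#' @export
pairwise_summary <- function(records, comparison = NULL) {
  tibble(
    comparison = comparison %||% NA_character_,
    n = nrow(records),
    pct_positive_gci = percent_positive(records, "delta_gci"),
    pct_positive_bpi = percent_positive(records, "delta_bpi"),
    mean_delta_gci = mean(records$delta_gci),
    mean_delta_bpi = mean(records$delta_bpi)
  )
}
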