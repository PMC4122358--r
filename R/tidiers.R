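# broom-style tidy()/glance() methods for the package's fitted objects.

#' Tidy an oxygen-consumption fit
#'
#' @param x An `o2_fit` from [consumption_rate()].
#' @param ... Unused.
#' @return One-row tibble: `species_id`, `rate_ug_h`, `mr0`, `r_squared`,
#'   `fall_fraction`, `valid`, `n_points`.
#' @method tidy o2_fit
#' @export
tidy.o2_fit <- function(x, ...) {
  tibble(species_id = x$species_id, rate_ug_h = x$rate_ug_h, mr0 = x$mr0,
         r_squared = x$r_squared, fall_fraction = x$fall_fraction,
         valid = x$valid, n_points = x$n_points)
}

#' @rdname tidy.o2_fit
#' @method glance o2_fit
#' @export
glance.o2_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, n_points = x$n_points,
         valid = x$valid, flags = paste(x$flags, collapse = ";"))
}

#' Tidy a Spearman correlation
#'
#' @param x A `spearman_cor` from [spearman_cor()].
#' @param ... Unused.
#' @return One-row tibble: `rho`, `p_value`, `n`, `p_method`.
#' @method tidy spearman_cor
#' @export
tidy.spearman_cor <- function(x, ...) {
  tibble(rho = x$rho, p_value = x$p_value, n = x$n, p_method = x$p_method)
}

#' Tidy a Student-Newman-Keuls test
#'
#' @param x An `snk_test` from [snk_test()].
#' @param ... Unused.
#' @return Tibble of pairwise decisions: `group_1`, `group_2`,
#'   `mean_diff`, `decision`.
#' @method tidy snk_test
#' @export
tidy.snk_test <- function(x, ...) {
  nm <- x$means$group
  mu <- setNames(x$means$mean, nm)
  pairs <- which(upper.tri(x$decision), arr.ind = TRUE)
  tibble(
    group_1 = nm[pairs[, 1]],
    group_2 = nm[pairs[, 2]],
    mean_diff = unname(mu[nm[pairs[, 2]]] - mu[nm[pairs[, 1]]]),
    decision = x$decision[pairs]
  )
}

#' @rdname tidy.snk_test
#' @method glance snk_test
#' @export
glance.snk_test <- function(x, ...) {
  tibble(n_groups = nrow(x$means), ms_error = x$ms_error,
         df_error = x$df_error, alpha = x$alpha,
         n_significant = sum(x$decision == "S") / 2)
}

#' Tidy class-frequency counts
#'
#' @param x A `class_counts` from [class_frequencies()].
#' @param ... Unused.
#' @return Tibble with `class`, `n`, `pct` and the comparison label.
#' @method tidy class_counts
#' @export
tidy.class_counts <- function(x, ...) {
  out <- as_tibble(x)
  out$comparison <- attr(x, "comparison") %||% NA_character_
  out
}

#' @rdname tidy.class_counts
#' @method glance class_counts
#' @export
glance.class_counts <- function(x, ...) {
  tibble(n_total = attr(x, "n_total"),
         top_class = as.character(x$class[which.max(x$n)]),
         top_pct = max(x$pct))
}
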