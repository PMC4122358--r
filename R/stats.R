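# Descriptive and inferential statistics used by the comparative analysis:
# moment skewness of GCi distributions, tie-aware Spearman rank
# correlation, and the Student-Newman-Keuls stepwise range test.

#' Moment coefficient of skewness
#'
#' Fisher-Pearson moment coefficient `g1 = m3 / m2^(3/2)` where `m2`, `m3`
#' are the central sample moments; `adjusted = TRUE` applies the
#' small-sample factor `sqrt(n(n-1))/(n-2)` (the G1 variant).
#'
#' @param x Numeric sample, `n >= 3`, non-degenerate.
#' @param adjusted Use the adjusted (G1) variant.
#' @return Skewness (SK).
#' @export
skewness <- function(x, adjusted = FALSE) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) abort("Skewness needs at least 3 observations.")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    abort("Skewness is undefined for a zero-variance sample.",
          class = "introdelta_undefined_value")
  }
  g1 <- mean((x - m)^3) / m2^1.5
  if (adjusted) g1 * sqrt(n * (n - 1)) / (n - 2) else g1
}

#' Spearman rank correlation
#'
#' Rho is the Pearson correlation of mid-ranks (tie-aware). The two-sided
#' p-value uses the t approximation with `n - 2` degrees of freedom by
#' default; `p_method = "permutation"` computes a permutation p-value
#' (exhaustive for `n <= 7`, otherwise `n_perm` seeded random
#' permutations), available for small samples.
#'
#' @param x,y Equal-length numeric vectors, `n >= 4`, non-constant.
#' @param p_method `"t"` or `"permutation"`.
#' @param n_perm Random permutations when exhaustive enumeration is
#'   impractical.
#' @param seed Seed for random permutations.
#' @return A `spearman_cor` object (fields `rho`, `p_value`, `n`,
#'   `p_method`); see [tidy.spearman_cor()].
#' @export
spearman_cor <- function(x, y, p_method = c("t", "permutation"),
                         n_perm = 20000, seed = 1L) {
  p_method <- arg_match(p_method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) abort("Spearman correlation needs n >= 4.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Spearman correlation is undefined for a constant vector.",
          class = "introdelta_undefined_value")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  p <- if (p_method == "t") {
    spearman_t_p(rho, n)
  } else {
    rho_perm <- if (n <= 7L) {
      perms <- permutations_all(n)
      apply(perms, 1L, function(ix) cor(rx, ry[ix]))
    } else {
      withr::with_seed(seed, replicate(n_perm, cor(rx, sample(ry))))
    }
    mean(abs(rho_perm) >= abs(rho) - 1e-12)
  }
  structure(list(rho = rho, p_value = p, n = n, p_method = p_method),
            class = "spearman_cor")
}

spearman_t_p <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tstat), df = n - 2)
}

permutations_all <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_all(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat(sprintf("<spearman_cor> rho = %.3f, p = %.4g (n = %d, %s)\n",
              x$rho, x$p_value, x$n, x$p_method))
  invisible(x)
}

#' Student-Newman-Keuls stepwise range test
#'
#' One-way ANOVA mean-square error, group means ranked, then stepwise
#' studentized-range comparisons: the span-`r` critical value is
#' `qtukey(1 - alpha, r, df_error)` (quantiles computed numerically from
#' the distribution function), and a comparison is declared non-significant
#' whenever any enclosing range was non-significant (the step-down
#' containment rule). Unequal group sizes use the harmonic-mean pairwise
#' standard error `sqrt(MSE/2 * (1/n_i + 1/n_j))`.
#'
#' @param data A data frame with a value and a group column, or a named
#'   list of numeric samples (>= 2 groups, each `n >= 2`).
#' @param value,group Column names when `data` is a data frame.
#' @param alpha Significance level of each stepwise comparison.
#' @return An `snk_test` object: `means` (tibble, sorted), `decision` (a
#'   symmetric character matrix of `"S"`/`"NS"` over groups), `ms_error`,
#'   `df_error`, `alpha`; see [tidy.snk_test()].
#' @export
snk_test <- function(data, value = "value", group = "group", alpha = 0.05) {
  groups <- if (is.data.frame(data)) {
    split(data[[value]], data[[group]])
  } else {
    data
  }
  groups <- lapply(groups, function(g) g[!is.na(g)])
  k <- length(groups)
  if (k < 2L) abort("SNK needs at least two groups.")
  if (any(lengths(groups) < 2L)) abort("Each group needs n >= 2.")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))

  ni <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  n_tot <- sum(ni)
  sse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_error <- n_tot - k
  if (df_error < 1L || sse == 0) {
    abort("Degenerate configuration: no residual variance for SNK.",
          class = "introdelta_undefined_value")
  }
  mse <- sse / df_error

  ord <- order(means)
  sorted <- means[ord]
  nm <- names(sorted)
  nn <- ni[ord]
  sig <- matrix(NA, k, k, dimnames = list(nm, nm))
  # spans from widest to narrowest; containment rule forces NS downward
  for (r in k:2) {
    for (i in seq_len(k - r + 1L)) {
      j <- i + r - 1L
      if (!is.na(sig[i, j])) next  # already forced NS by a wider span
      se <- sqrt(mse / 2 * (1 / nn[i] + 1 / nn[j]))
      q <- (sorted[j] - sorted[i]) / se
      crit <- qtukey(1 - alpha, nmeans = r, df = df_error)
      if (q > crit) {
        sig[i, j] <- sig[j, i] <- TRUE
      } else {
        sig[i:j, i:j] <- FALSE  # all enclosed comparisons NS
      }
    }
  }
  diag(sig) <- FALSE
  decision <- matrix(ifelse(sig, "S", "NS"), k, k, dimnames = dimnames(sig))
  diag(decision) <- "-"
  structure(
    list(means = tibble(group = nm, n = as.integer(nn), mean = unname(sorted)),
         decision = decision, ms_error = mse, df_error = df_error,
         alpha = alpha),
    class = "snk_test")
}

#' @export
print.snk_test <- function(x, ...) {
  cat(sprintf("<snk_test> %d groups, MSE %.4g (df %d), alpha %.3g\n",
              nrow(x$means), x$ms_error, x$df_error, x$alpha))
  print(x$decision, quote = FALSE)
  invisible(x)
}
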