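# Fixtures and independent oracles used across the suite. Each oracle is
# deliberately coded by a different route than the implementation it
# checks.

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# DNA string with an exact G+C count (for constructions whose GC must be
# known without rounding)
dna_exact_gc <- function(len, gc_count) {
  v <- sample(c("A", "T"), len, replace = TRUE)
  if (gc_count > 0) v[sample.int(len, gc_count)] <- sample(c("G", "C"), gc_count, replace = TRUE)
  paste(v, collapse = "")
}

rand_protein <- function(n) {
  paste(c("M", sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                      n - 1, replace = TRUE)), collapse = "")
}

# --- binomial tail: pmf by multiplicative recurrence, no dbinom ---------
binom_tail_recurrence <- function(n, p) {
  pmf <- numeric(n + 1)
  pmf[1] <- (1 - p)^n
  for (k in 0:(n - 1)) {
    pmf[k + 2] <- pmf[k + 1] * (n - k) / (k + 1) * p / (1 - p)
  }
  rev(cumsum(rev(pmf)))  # tail[k+1] = P(X >= k)
}

# --- Benjamini-Hochberg from the definition -----------------------------
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(ord == i)  # rank of p[i]
    adj[i] <- min(1, min(m * p[ord][r:m] / (r:m)))
  }
  adj
}

# --- brute-force RBH: intersection of unique-argmax maps ----------------
brute_rbh <- function(hits_ab, hits_ba) {
  argmax_map <- function(h) {
    out <- list()
    for (q in unique(h$query_id)) {
      rows <- h[h$query_id == q, ]
      best <- rows[rows$score == max(rows$score), ]
      if (nrow(best) == 1) out[[q]] <- best$subject_id
    }
    out
  }
  fwd <- argmax_map(hits_ab)
  rev_ <- argmax_map(hits_ba)
  pairs <- character(0)
  for (a in names(fwd)) {
    b <- fwd[[a]]
    if (!is.null(rev_[[b]]) && rev_[[b]] == a) {
      pairs <- c(pairs, paste(a, b, sep = "->"))
    }
  }
  sort(pairs)
}

# --- reference SNK: ptukey p-values + check-all-containing-ranges rule --
ref_snk <- function(groups, alpha = 0.05) {
  k <- length(groups)
  ni <- lengths(groups)
  mse <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2))) /
    (sum(ni) - k)
  dfe <- sum(ni) - k
  mu <- sort(vapply(groups, mean, numeric(1)))
  nm <- names(mu)
  nn <- ni[nm]
  sig_span <- function(i, j) {
    q <- (mu[j] - mu[i]) / sqrt(mse / 2 * (1 / nn[i] + 1 / nn[j]))
    pv <- 1 - ptukey(q, nmeans = j - i + 1, df = dfe)
    pv < alpha
  }
  dec <- matrix("-", k, k, dimnames = list(nm, nm))
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      # significant iff every containing span tests significant
      ok <- TRUE
      for (a in 1:i) {
        for (b in j:k) {
          if (!sig_span(a, b)) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      dec[i, j] <- dec[j, i] <- if (ok) "S" else "NS"
    }
  }
  dec
}

# skew-normal sampler (location-scale of the |N| + N representation) and
# its closed-form population skewness
rsn_shape <- function(n, shape) {
  d <- shape / sqrt(1 + shape^2)
  d * abs(rnorm(n)) + sqrt(1 - d^2) * rnorm(n)
}
sn_pop_skewness <- function(shape) {
  d <- shape / sqrt(1 + shape^2)
  b <- d * sqrt(2 / pi)
  (4 - pi) / 2 * b^3 / (1 - b^2)^1.5
}

# toy two-species delta table with known composition
toy_delta_records <- function(delta_bpi, delta_gci) {
  n <- length(delta_bpi)
  out <- tibble::tibble(
    gene_m = sprintf("m%03d", seq_len(n)),
    gene_z = sprintf("z%03d", seq_len(n)),
    delta_bpi = delta_bpi, delta_gci = delta_gci,
    masked_variant = "before"
  )
  attr(out, "species") <- c("m", "z")
  out
}

# small deterministic intron-pair table (both orientations derivable)
toy_intron_pairs <- function(bpi_m, gci_m, bpi_z, gci_z) {
  n <- length(bpi_m)
  tibble::tibble(
    gene_m = sprintf("m%03d", seq_len(n)),
    gene_z = sprintf("z%03d", seq_len(n)),
    sequence_m = NA_character_, bpi_m = bpi_m, gci_m = gci_m,
    sequence_z = NA_character_, bpi_z = bpi_z, gci_z = gci_z
  )
}

swap_orientation <- function(intron_pairs) {
  tibble::tibble(
    gene_m = intron_pairs$gene_z, gene_z = intron_pairs$gene_m,
    sequence_m = intron_pairs$sequence_z, bpi_m = intron_pairs$bpi_z,
    gci_m = intron_pairs$gci_z,
    sequence_z = intron_pairs$sequence_m, bpi_z = intron_pairs$bpi_m,
    gci_z = intron_pairs$gci_m
  )
}

# repeat library whose elements have an exact GC percent
exact_gc_library <- function(n_elements, len, gc_pct, prefix = "rep") {
  els <- vapply(seq_len(n_elements), function(i) {
    dna_exact_gc(len, round(gc_pct / 100 * len))
  }, character(1))
  repeat_library(setNames(els, paste0(prefix, seq_len(n_elements))))
}
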