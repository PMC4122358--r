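test_that("deltas are oriented first-species-minus-second", {
  ip <- toy_intron_pairs(bpi_m = c(1000L, 500L), gci_m = c(40, 40),
                         bpi_z = c(800L, 500L), gci_z = c(42, 40))
  d <- compute_deltas(ip)
  expect_equal(d$delta_bpi, c(200L, 0L))
  expect_equal(d$delta_gci, c(-2, 0))
  expect_error(
    compute_deltas(toy_intron_pairs(1L, NA_real_, 1L, 40)),
    class = "introdelta_usage_error")
})

test_that("the negligible-delta filter removes below-threshold records, boundary kept", {
  d <- toy_delta_records(
    delta_bpi = c(-50, 100, 150, -200, 99),
    delta_gci = c(5, 0.1, 0.05, -3, 4))
  f <- filter_deltas(d)
  # removed: |bp|=50; |gc|=0.05; |bp|=99. boundary (100, 0.1) retained.
  expect_equal(nrow(f), 2L)
  expect_equal(attr(f, "n_removed"), 3L)
  expect_equal(removed_fraction(f), 60)
  # AND rule removes only when both are negligible
  f_and <- filter_deltas(d, rule = "and")
  expect_equal(nrow(f_and), 5L)
  d2 <- toy_delta_records(c(-50, 300), c(0.05, 2))
  expect_equal(nrow(filter_deltas(d2, rule = "and")), 1L)
})

test_that("percent positive and its complement cross-foot to one hundred", {
  d <- toy_delta_records(delta_bpi = c(rep(300, 7), rep(-300, 3)),
                         delta_gci = c(rep(-1, 4), rep(1, 6)))
  expect_equal(percent_positive(d, "delta_bpi"), 70)
  expect_equal(percent_positive(d, "delta_gci"), 60)
  withr::with_seed(4, {
    for (i in 1:10) {
      n <- sample(5:50, 1)
      d <- toy_delta_records(sample(c(-1, 1), n, TRUE) * (100 + rpois(n, 50)),
                             sample(c(-1, 1), n, TRUE) * runif(n, 0.1, 5))
      expect_equal(percent_positive(d, "delta_gci") +
                     (100 - percent_positive(d, "delta_gci")), 100)
    }
  })
  expect_error(percent_positive(toy_delta_records(numeric(), numeric())),
               class = "introdelta_undefined_value")
})

test_that("sign classes map per definition: N/P, N/N, P/N, P/P", {
  d <- toy_delta_records(delta_bpi = c(-200, -200, 200, 200),
                         delta_gci = c(1.5, -1.5, -1.5, 1.5))
  cl <- classify_deltas(d)
  expect_equal(as.character(cl$class), c("N/P", "N/N", "P/N", "P/P"))
  expect_error(classify_deltas(toy_delta_records(0, 1)),
               class = "introdelta_contract_violation")
})

test_that("class frequencies count and cross-foot to 100", {
  d <- toy_delta_records(delta_bpi = c(-200, -200, 200, 200),
                         delta_gci = c(1.5, -1.5, -1.5, 1.5))
  cf <- class_frequencies(classify_deltas(d))
  expect_equal(cf$pct, rep(25, 4))
  expect_equal(sum(cf$pct), 100)
  allnp <- class_frequencies(classify_deltas(
    toy_delta_records(rep(-200, 6), rep(2, 6))))
  expect_equal(allnp$pct, c(100, 0, 0, 0))
})

test_that("multinomial class draws are recovered within 3 binomial SD", {
  withr::with_seed(17, {
    probs <- c(0.6, 0.2, 0.05, 0.15)
    n <- 2000
    lab <- sample(1:4, n, TRUE, prob = probs)
    signs <- list(c(-1, 1), c(-1, -1), c(1, -1), c(1, 1))
    sb <- vapply(lab, function(l) signs[[l]][1], numeric(1))
    sg <- vapply(lab, function(l) signs[[l]][2], numeric(1))
    d <- toy_delta_records(sb * (100 + rpois(n, 200)), sg * runif(n, 0.2, 4))
    cf <- class_frequencies(classify_deltas(d))
    for (i in 1:4) {
      sd_i <- sqrt(probs[i] * (1 - probs[i]) / n)
      expect_lt(abs(cf$pct[i] / 100 - probs[i]), 3 * sd_i)
    }
  })
})

test_that("exact binomial upper tail matches closed forms and the recurrence oracle", {
  expect_equal(binom_upper_tail(3, 3, 0.25), 0.25^3)
  expect_equal(binom_upper_tail(0, 10, 0.25), 1)
  expect_equal(binom_upper_tail(100, 100, 0.5), 0.5^100)
  # independent pmf-recurrence oracle
  for (p in c(0.25, 0.5)) {
    for (n in c(10, 57, 100)) {
      tail_or <- binom_tail_recurrence(n, p)
      got <- vapply(0:n, binom_upper_tail, numeric(1), n = n, p = p)
      expect_equal(got, tail_or, tolerance = 1e-12)
      # monotone decreasing in k
      expect_true(all(diff(got) <= 0))
    }
  }
  # regularized incomplete beta identity: P(X >= k) = I_p(k, n-k+1)
  for (k in c(1, 10, 59)) {
    expect_equal(binom_upper_tail(k, 100, 0.25),
                 pbeta(0.25, k, 100 - k + 1), tolerance = 1e-12)
  }
  expect_error(binom_upper_tail(1, 10, 0), class = "introdelta_parameter_error")
})

test_that("the dominant-class test uses the top class and supports the top-two null", {
  d <- toy_delta_records(c(rep(-200, 8), rep(200, 2)),
                         c(rep(2, 8), rep(-2, 2)))
  cf <- class_frequencies(classify_deltas(d))
  bt <- binomial_test_top_class(cf)
  expect_equal(bt$top_class, "N/P")
  expect_equal(bt$k, 8L); expect_equal(bt$n, 10L)
  expect_equal(bt$p_value, binom_upper_tail(8, 10, 0.25))
  bt2 <- binomial_test_top_class(cf, null = "top2")
  expect_equal(bt2$n, 10L)  # N/P + P/N
  expect_equal(bt2$null_p, 0.5)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(adjust_fdr(0.02), 0.02)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  withr::with_seed(31, {
    for (i in 1:10) {
      p <- runif(sample(3:20, 1))
      expect_equal(adjust_fdr(p), bh_brute(p), tolerance = 1e-12)
    }
  })
})

test_that("orientation reversal is a full antisymmetry of the analysis", {
  withr::with_seed(23, {
    sim <- generate_species_pair(synth_config(seed = 23, n_genes = 120))
    ip <- extend_to_introns(sim$truth$pairs[, c("gene_m", "gene_z")],
                            sim$ds_m, sim$ds_z)
    rev_ip <- swap_orientation(ip)
    d_f <- compute_deltas(ip)
    d_r <- compute_deltas(rev_ip)
    expect_equal(d_r$delta_bpi, -d_f$delta_bpi)
    expect_equal(d_r$delta_gci, -d_f$delta_gci)
    f_f <- filter_deltas(d_f); f_r <- filter_deltas(d_r)
    expect_equal(attr(f_f, "n_removed"), attr(f_r, "n_removed"))
    expect_equal(percent_positive(f_r, "delta_gci"),
                 100 - percent_positive(f_f, "delta_gci"))
    cf_f <- class_frequencies(classify_deltas(f_f))
    cf_r <- class_frequencies(classify_deltas(f_r))
    swap <- c(`N/P` = "P/N", `N/N` = "P/P", `P/N` = "N/P", `P/P` = "N/N")
    expect_equal(cf_r$n[match(swap, cf_r$class)], cf_f$n)
  })
})
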