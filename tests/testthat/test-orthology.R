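test_that("identical sequences are their own best hits with maximal score", {
  withr::with_seed(1, {
    p <- setNames(vapply(rep(50, 3), rand_protein, character(1)),
                  c("a1", "a2", "a3"))
    hits <- all_vs_all_hits(p, p, score_min = 10)
    best <- hits |> dplyr::group_by(query_id) |> dplyr::slice_max(score, n = 1)
    expect_identical(best$subject_id, best$query_id)
  })
})

test_that("hits below the score floor are dropped and empty input warns", {
  withr::with_seed(2, {
    a <- setNames(vapply(rep(60, 2), rand_protein, character(1)), c("a1", "a2"))
    b <- setNames(vapply(rep(60, 2), rand_protein, character(1)), c("b1", "b2"))
    strict <- all_vs_all_hits(a, b, score_min = 1e6)
    expect_equal(nrow(strict), 0L)
  })
  expect_warning(h <- all_vs_all_hits(character(), character()), "Empty")
  expect_equal(nrow(h), 0L)
})

test_that("reciprocal best hits require mutual unique argmax", {
  mk <- function(q, s, sc) tibble::tibble(query_id = q, subject_id = s,
                                          score = sc, evalue = NA_real_)
  # symmetric best hits give two pairs
  ab <- mk(c("a1", "a2"), c("b1", "b2"), c(100, 90))
  ba <- mk(c("b1", "b2"), c("a1", "a2"), c(100, 90))
  rb <- reciprocal_best_hits(ab, ba)
  expect_equal(nrow(rb), 2L)

  # a1 -> b1 but b1 -> a2: no pair involving b1
  ab2 <- mk(c("a1", "a2"), c("b1", "b2"), c(100, 90))
  ba2 <- mk(c("b1", "b2"), c("a2", "a2"), c(100, 90))
  rb2 <- reciprocal_best_hits(ab2, ba2)
  expect_false("b1" %in% rb2$gene_z)

  # tie for best drops the gene
  ab3 <- mk(c("a1", "a1"), c("b1", "b2"), c(100, 100))
  ba3 <- mk(c("b1", "b2"), c("a1", "a1"), c(100, 80))
  expect_equal(nrow(reciprocal_best_hits(ab3, ba3)), 0L)

  # e-value threshold filters imported hits
  ab4 <- mk("a1", "b1", 100); ab4$evalue <- 1e-5
  ba4 <- mk("b1", "a1", 100); ba4$evalue <- 1e-20
  expect_equal(nrow(reciprocal_best_hits(ab4, ba4, evalue_max = 1e-10)), 0L)
})

test_that("RBH equals the brute-force argmax-map intersection on random tables", {
  withr::with_seed(11, {
    for (rep in 1:25) {
      na <- sample(3:8, 1); nb <- sample(3:8, 1)
      hits_ab <- tibble::tibble(
        query_id = rep(paste0("a", 1:na), each = nb),
        subject_id = rep(paste0("b", 1:nb), times = na),
        score = sample(1:40, na * nb, replace = TRUE),
        evalue = NA_real_)
      hits_ba <- tibble::tibble(
        query_id = rep(paste0("b", 1:nb), each = na),
        subject_id = rep(paste0("a", 1:na), times = nb),
        score = sample(1:40, na * nb, replace = TRUE),
        evalue = NA_real_)
      got <- reciprocal_best_hits(hits_ab, hits_ba)
      expect_identical(sort(paste(got$gene_m, got$gene_z, sep = "->")),
                       brute_rbh(hits_ab, hits_ba))
    }
  })
})

test_that("RBH is symmetric in species order and bounded by min set size", {
  withr::with_seed(5, {
    a <- setNames(vapply(sample(60:90, 6, TRUE), rand_protein, character(1)),
                  paste0("a", 1:6))
    b <- setNames(vapply(sample(60:90, 4, TRUE), rand_protein, character(1)),
                  paste0("b", 1:4))
    hab <- all_vs_all_hits(a, b, score_min = 15)
    hba <- all_vs_all_hits(b, a, score_min = 15)
    fwd <- reciprocal_best_hits(hab, hba)
    bwd <- reciprocal_best_hits(hba, hab)
    expect_lte(nrow(fwd), 4L)
    expect_identical(sort(paste(fwd$gene_m, fwd$gene_z)),
                     sort(paste(bwd$gene_z, bwd$gene_m)))
  })
})

test_that("RBH recovers the true pairing on mutated-copy proteomes", {
  withr::with_seed(21, {
    for (rep in 1:3) {
      n <- 12
      pa <- setNames(vapply(sample(70:120, n, TRUE), rand_protein, character(1)),
                     paste0("a", 1:n))
      mutate1 <- function(p, rate = 0.05) {
        v <- strsplit(p, "")[[1]]
        idx <- which(runif(length(v)) < rate)
        aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
        for (i in idx) v[i] <- sample(setdiff(aa, v[i]), 1)
        paste(v, collapse = "")
      }
      pb <- setNames(vapply(pa, mutate1, character(1)), paste0("b", 1:n))
      perm <- sample(n)
      pb <- pb[perm]
      rb <- reciprocal_best_hits(all_vs_all_hits(pa, pb),
                                 all_vs_all_hits(pb, pa))
      expect_equal(nrow(rb), n)
      expect_identical(substring(rb$gene_m, 2), substring(rb$gene_z, 2))
    }
  })
})

test_that("tabular hit files round-trip and malformed rows name their line", {
  dir <- withr::local_tempdir()
  hits <- tibble::tibble(
    query_id = c("q1", "q2"), subject_id = c("s1", "s2"),
    pct_identity = c(98.5, 77.1), length = c(120L, 80L),
    mismatches = c(1L, 18L), gap_opens = c(0L, 1L),
    qstart = c(1L, 3L), qend = c(120L, 82L), sstart = c(1L, 2L),
    send = c(120L, 81L), evalue = c(1e-50, 1e-12), score = c(240, 101))
  p <- file.path(dir, "hits.tsv")
  export_tabular_hits(hits, p)
  back <- import_tabular_hits(p)
  expect_equal(back, hits)

  bad <- file.path(dir, "bad.tsv")
  writeLines(c(paste(rep("x", 12), collapse = "\t"),
               paste(rep("y", 11), collapse = "\t")), bad)
  expect_error(import_tabular_hits(bad), "line 2",
               class = "introdelta_format_error")
})

test_that("orthology extends to introns, dropping intronless members with a count", {
  sim <- generate_species_pair(synth_config(seed = 8, n_genes = 20))
  pairs <- sim$truth$pairs[, c("gene_m", "gene_z")]
  # blank out introns for 4 species-z genes
  ds_z <- sim$ds_z
  victims <- ds_z$introns$gene_id[1:4]
  sel <- ds_z$introns$gene_id %in% victims
  ds_z$introns$sequence[sel] <- ""
  ds_z$introns$bpi[sel] <- 0L
  ds_z$introns$gci[sel] <- NA_real_
  expect_message(ip <- extend_to_introns(pairs, sim$ds_m, ds_z), "4")
  expect_equal(nrow(ip), 16L)
  expect_equal(attr(ip, "n_dropped"), 4L)
  expect_error(extend_to_introns(tibble::tibble(gene_m = "nope", gene_z = "nah"),
                                 sim$ds_m, ds_z),
               class = "introdelta_lookup_error")
})
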