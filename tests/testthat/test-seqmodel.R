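test_that("gc_content follows the molar-ratio definition and masking conventions", {
  expect_equal(gc_content("GCAT"), 50)
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("GCATNN"), 50)  # N excluded from both counts
  expect_equal(gc_content("gcat"), 50)    # case-insensitive
  expect_equal(gc_content("GCatNN", exclude_soft = TRUE), 100)
  expect_error(gc_content("NNNN"), class = "introdelta_undefined_value")
})

test_that("gc_content is invariant under reverse complement and case change", {
  withr::with_seed(42, {
    for (i in 1:20) {
      s <- rand_dna(sample(50:500, 1), gc = runif(1, 0.2, 0.8))
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      expect_equal(gc_content(s), gc_content(rc))
      expect_equal(gc_content(s), gc_content(tolower(s)))
    }
  })
})

test_that("concatenation identities hold exactly for length and GC", {
  withr::with_seed(7, {
    for (i in 1:10) {
      parts <- replicate(sample(2:6, 1), rand_dna(sample(20:200, 1)))
      whole <- paste(parts, collapse = "")
      expect_identical(nchar(whole), sum(nchar(parts)))
      expect_equal(gc_content(whole),
                   sum(gc_content(parts) * nchar(parts)) / sum(nchar(parts)))
    }
  })
})

test_that("ambiguity detection flags any non-ACGT character", {
  expect_false(has_base_ambiguity("ACGT"))
  expect_true(has_base_ambiguity("ACRT"))
  expect_true(has_base_ambiguity("ACGTN"))
  withr::with_seed(1, expect_false(has_base_ambiguity(rand_dna(1000))))
})

test_that("internal stop codons are detected in frame, terminal stops ignored", {
  expect_false(has_internal_stop("ATGAAATAG"))
  expect_true(has_internal_stop("ATGTAAAAATAG"))
  expect_true(is.na(has_internal_stop("ATGAA")))  # malformed: not a codon multiple
  # stop triplet out of frame is not a stop
  expect_false(has_internal_stop("ATGATAAGGTAG"))
})

test_that("internal-intron extraction respects the CDS span and strand", {
  # contig: exon1(UTR) - intronA - exon2(CDS) - intronB - exon3(CDS)
  contig <- paste0(
    "TTTTT",            # exon1  1-5   pure UTR
    "GGGGGGGGGG",       # intronA 6-15 (flanking: excluded)
    "ATGAA",            # exon2 16-20  CDS starts
    "CCCCCCCC",         # intronB 21-28 (internal)
    "AGGTTTTAA"         # exon3 29-37  CDS ends
  )
  gm <- gene_model("g1", "sp", "+",
                   exon_intervals = rbind(c(1, 5), c(16, 20), c(29, 37)),
                   cds_intervals = rbind(c(16, 20), c(29, 37)),
                   seq = contig)
  intr <- extract_internal_introns(gm)
  expect_equal(intr$sequence, "CCCCCCCC")
  expect_equal(intr$n_introns, 1L)
  expect_equal(intr$bpi, 8L)

  # minus strand: intron equals reverse complement of the genomic gap,
  # transcription order reversed
  contig2 <- paste0("ATGAA", "GGGGCCAA", "TTTAA")
  gm2 <- gene_model("g2", "sp", "-",
                    exon_intervals = rbind(c(1, 5), c(14, 18)),
                    cds_intervals = rbind(c(1, 5), c(14, 18)),
                    seq = contig2)
  intr2 <- extract_internal_introns(gm2)
  expect_equal(intr2$sequence,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString("GGGGCCAA"))))

  # gene whose only intron lies in the 5' UTR: empty intronic sequence
  gm3 <- gene_model("g3", "sp", "+",
                    exon_intervals = rbind(c(1, 5), c(16, 37)),
                    cds_intervals = rbind(c(16, 37)),
                    seq = contig)
  intr3 <- extract_internal_introns(gm3)
  expect_equal(intr3$bpi, 0L)
  expect_equal(intr3$n_introns, 0L)

  # additivity: three CDS-internal introns of 100 bp each give bpi = 300
  i100 <- strrep("G", 100)
  contig4 <- paste0("ATG", i100, "AAA", i100, "CCC", i100, "TAA")
  ex <- rbind(c(1, 3), c(104, 106), c(207, 209), c(310, 312))
  gm4 <- gene_model("g4", "sp", "+", ex, ex, contig4)
  expect_equal(extract_internal_introns(gm4)$bpi, 300L)
})

test_that("gene models validate their coordinate invariants", {
  expect_error(gene_model("g", "s", "+", rbind(c(1, 10)), rbind(c(5, 20)),
                          strrep("A", 15)),
               class = "introdelta_coordinate_error")
  expect_error(gene_model("g", "s", "+", rbind(c(1, 50)), NULL,
                          strrep("A", 20)),
               class = "introdelta_coordinate_error")
  expect_error(gene_model("g", "s", "+",
                          matrix(integer(), ncol = 2), NULL, "ACGT"))
})

test_that("a written synthetic dataset round-trips through the loader", {
  sim <- generate_species_pair(synth_config(seed = 3, n_genes = 10))
  dir <- withr::local_tempdir()
  run <- write_synthetic_run(sim, dir)
  for (side in c("species_m", "species_z")) {
    ds0 <- if (side == "species_m") sim$ds_m else sim$ds_z
    ds1 <- load_species_dataset(file.path(run, paste0(side, ".fa")),
                                file.path(run, paste0(side, ".gff3")),
                                species_id = side)
    o0 <- ds0$introns[order(ds0$introns$gene_id), ]
    o1 <- ds1$introns[order(ds1$introns$gene_id), ]
    expect_identical(o1$sequence, o0$sequence)
    expect_equal(o1$gci, o0$gci)
    expect_identical(sort(unname(ds1$cds_seqs)), sort(unname(ds0$cds_seqs)))
    expect_equal(ds1$gcg, ds0$gcg)
  }
  # intron table TSV round-trip
  p <- file.path(dir, "introns.tsv")
  write_intron_table(sim$ds_m, p)
  back <- read_intron_table(p)
  expect_equal(back$bpi, sim$ds_m$introns$bpi)
  expect_equal(back$gci, sim$ds_m$introns$gci)
})

test_that("single-exon genes yield no intronic sequence", {
  gm <- gene_model("g1", "sp", "+", rbind(c(1, 9)), rbind(c(1, 9)),
                   "ATGAAATAG")
  intr <- extract_internal_introns(gm)
  expect_equal(intr$n_introns, 0L)
  expect_equal(intr$sequence, "")
})

test_that("dataset_summary reports GCg, mean GCi and mean bpi", {
  ds <- species_dataset(
    "sp",
    genes = tibble::tibble(gene_id = c("a", "b"), strand = "+",
                           has_ambiguity = FALSE, malformed_cds = FALSE,
                           internal_stop = FALSE, n_introns = 1L),
    cds_seqs = c(a = "ATGTAA", b = "ATGTAA"),
    protein_seqs = c(a = "M", b = "M"),
    introns = tibble::tibble(
      gene_id = c("a", "b"), species_id = "sp",
      sequence = c("GCGC", strrep("AT", 2)),
      bpi = c(4L, 4L), gci = c(100, 0), n_introns = 1L),
    gcg = 50)
  s <- dataset_summary(ds)
  expect_equal(s$mean_gci, 50)
  expect_equal(s$mean_bpi, 4)
  expect_equal(s$gcg, 50)
})

test_that("malformed GFF3 raises a format error", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa")
  writeLines(c(">chr1", "ACGTACGTACGT"), fa)
  bad <- file.path(dir, "bad.gff3")
  writeLines(c("##gff-version 3", "not a gff line at all"), bad)
  expect_error(load_species_dataset(fa, bad),
               class = "introdelta_format_error")
})
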