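# SpeciesDataset: one species' gene models with derived CDS, protein and
# concatenated internal-intron sequences plus genome GC (GCg).

#' Construct a species dataset
#'
#' Bundles a species' per-gene QC table, coding/protein/intronic sequences
#' and the genome GC percent (GCg). Most users obtain one via
#' [load_species_dataset()] or [generate_species_pair()].
#'
#' @param species_id Species identifier.
#' @param genes Tibble with one row per gene: `gene_id`, `strand`,
#'   `has_ambiguity`, `malformed_cds`, `internal_stop`, `n_introns`.
#' @param cds_seqs,protein_seqs Named character vectors keyed by `gene_id`.
#' @param introns Tibble of concatenated internal-intron records
#'   (`gene_id`, `species_id`, `sequence`, `bpi`, `gci`, `n_introns`).
#' @param gcg Genome GC percent in `[0, 100]`.
#' @return Object of class `species_dataset`.
#' @export
species_dataset <- function(species_id, genes, cds_seqs, protein_seqs,
                            introns, gcg) {
  genes <- as_tibble(genes)
  introns <- as_tibble(introns)
  stopifnot(is.numeric(gcg), gcg >= 0, gcg <= 100)
  if (!all(introns$gene_id %in% genes$gene_id)) {
    abort("Every intronic sequence must reference a known gene.")
  }
  structure(
    list(species_id = species_id, genes = genes, cds_seqs = cds_seqs,
         protein_seqs = protein_seqs, introns = introns, gcg = gcg),
    class = "species_dataset"
  )
}

#' @export
print.species_dataset <- function(x, ...) {
  cat(sprintf("<species_dataset> %s: %d genes, %d with internal introns, GCg %.2f%%\n",
              x$species_id, nrow(x$genes), sum(x$introns$bpi > 0), x$gcg))
  invisible(x)
}

#' Load a species dataset from a genome FASTA and GFF3 annotation
#'
#' Selects one transcript per protein-coding gene (longest total CDS, ties
#' broken by lexicographically smallest transcript id), extracts the CDS
#' (spliced, reverse complemented on the minus strand), translates it, and
#' concatenates the internal introns per [extract_internal_introns()]. QC
#' flags record base ambiguity (in CDS or introns), malformed CDS (length
#' not a multiple of 3) and internal stop codons; flagged genes are
#' excluded from orthology input downstream.
#'
#' @param genome_fasta Path to a (multi-)FASTA genome.
#' @param annotation_gff Path to a GFF3 annotation using `gene`,
#'   `mRNA`/`transcript`, `exon` and `CDS` features linked by `ID`/`Parent`.
#' @param species_id Identifier; defaults to the FASTA file stem.
#' @param internal_rule Passed to [extract_internal_introns()].
#' @return A [species_dataset()].
#' @export
load_species_dataset <- function(genome_fasta, annotation_gff,
                                 species_id = NULL,
                                 internal_rule = "cds_span") {
  species_id <- species_id %||%
    sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(genome_fasta))
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))

  gff <- tryCatch(
    rtracklayer::import(annotation_gff, format = "gff3"),
    error = function(e) abort(
      sprintf("Unparseable GFF3 '%s': %s", annotation_gff, conditionMessage(e)),
      class = "introdelta_format_error")
  )
  feat <- as_tibble(as.data.frame(gff)) |>
    mutate(
      seqnames = as.character(.data$seqnames),
      strand = as.character(.data$strand),
      type = as.character(.data$type),
      Parent = vapply(.data$Parent, function(p)
        if (length(p)) as.character(p)[1] else NA_character_, character(1))
    )
  if (!all(unique(feat$seqnames) %in% names(genome))) {
    abort("GFF3 references sequence names absent from the FASTA.",
          class = "introdelta_format_error")
  }

  tx <- feat |>
    filter(.data$type %in% c("mRNA", "transcript")) |>
    transmute(tx_id = .data$ID, gene_id = .data$Parent,
              strand = .data$strand, seqnames = .data$seqnames)
  if (nrow(tx) == 0L) {
    abort("GFF3 contains no mRNA/transcript features.",
          class = "introdelta_format_error")
  }
  parts <- feat |>
    filter(.data$type %in% c("exon", "CDS"), !is.na(.data$Parent)) |>
    select("type", "start", "end", tx_id = "Parent")

  # canonical transcript: longest summed CDS, lexicographic tie-break
  cds_len <- parts |>
    filter(.data$type == "CDS") |>
    group_by(.data$tx_id) |>
    summarise(cds_len = sum(.data$end - .data$start + 1L), .groups = "drop")
  canonical <- tx |>
    inner_join(cds_len, by = "tx_id") |>
    arrange(.data$gene_id, desc(.data$cds_len), .data$tx_id) |>
    group_by(.data$gene_id) |>
    slice(1L) |>
    ungroup()

  contig_chr <- lapply(as.character(genome), identity)
  rows <- vector("list", nrow(canonical))
  intron_rows <- vector("list", nrow(canonical))
  cds_seqs <- character(nrow(canonical))
  for (i in seq_len(nrow(canonical))) {
    g <- canonical[i, ]
    p <- parts[parts$tx_id == g$tx_id, ]
    gm <- gene_model(
      gene_id = g$gene_id, species_id = species_id, strand = g$strand,
      exon_intervals = as.matrix(p[p$type == "exon", c("start", "end")]),
      cds_intervals = as.matrix(p[p$type == "CDS", c("start", "end")]),
      seq = contig_chr[[g$seqnames]]
    )
    cds <- spliced_sequence(gm$seq, gm$cds_intervals, gm$strand)
    intr <- extract_internal_introns(gm, internal_rule = internal_rule)
    cds_seqs[i] <- cds
    intron_rows[[i]] <- intr
    rows[[i]] <- tibble(
      gene_id = g$gene_id, tx_id = g$tx_id, strand = g$strand,
      n_exons = sum(p$type == "exon"),
      has_ambiguity = has_base_ambiguity(cds) ||
        (intr$bpi > 0 && has_base_ambiguity(intr$sequence)),
      malformed_cds = nchar(cds) %% 3L != 0L,
      internal_stop = isTRUE(has_internal_stop(cds)),
      n_introns = intr$n_introns
    )
  }
  genes <- list_rbind(rows)
  introns <- list_rbind(intron_rows)
  names(cds_seqs) <- genes$gene_id
  protein_seqs <- translate_cds(cds_seqs)

  species_dataset(
    species_id = species_id, genes = genes, cds_seqs = cds_seqs,
    protein_seqs = protein_seqs, introns = introns,
    gcg = gc_content(paste(as.character(genome), collapse = ""))
  )
}

spliced_sequence <- function(contig, intervals, strand) {
  if (nrow(intervals) == 0L) return("")
  s <- paste(substring(contig, intervals[, 1L], intervals[, 2L]), collapse = "")
  if (strand == "-") revcomp(s) else s
}

translate_cds <- function(cds_seqs) {
  out <- setNames(rep(NA_character_, length(cds_seqs)), names(cds_seqs))
  ok <- nchar(cds_seqs) %% 3L == 0L & nchar(cds_seqs) >= 3L &
    !has_base_ambiguity(cds_seqs)
  if (any(ok)) {
    aa <- suppressWarnings(as.character(
      Biostrings::translate(Biostrings::DNAStringSet(toupper(cds_seqs[ok])))
    ))
    out[ok] <- sub("\\*$", "", aa)
  }
  out
}

#' Genes passing sequence QC
#'
#' Genes whose CDS is well-formed (length divisible by 3), free of internal
#' stop codons and whose sequences carry no base ambiguity: the orthology
#' input set.
#'
#' @param ds A [species_dataset()].
#' @return Character vector of gene ids.
#' @export
qc_pass_genes <- function(ds) {
  stopifnot(inherits(ds, "species_dataset"))
  g <- ds$genes
  g$gene_id[!g$has_ambiguity & !g$malformed_cds & !g$internal_stop]
}

#' Summarise a species dataset
#'
#' Species-level summary of base composition and intron length: genome GC
#' (GCg), mean intronic GC (GCi), mean concatenated internal-intron length
#' (bpi) and skewness of the GCi distribution — the per-species quantities
#' the comparative analysis ranks species by.
#'
#' @param ds A [species_dataset()].
#' @return One-row tibble: `species_id`, `n_genes`, `n_with_introns`,
#'   `gcg`, `mean_gci`, `mean_bpi`, `sk_gci`.
#' @export
dataset_summary <- function(ds) {
  stopifnot(inherits(ds, "species_dataset"))
  intr <- ds$introns[ds$introns$bpi > 0, ]
  if (nrow(intr) == 0L) abort("Dataset has no intronic sequences.")
  tibble(
    species_id = ds$species_id,
    n_genes = nrow(ds$genes),
    n_with_introns = nrow(intr),
    gcg = ds$gcg,
    mean_gci = mean(intr$gci),
    mean_bpi = mean(intr$bpi),
    sk_gci = if (nrow(intr) >= 3 && sd(intr$gci) > 0) skewness(intr$gci) else NA_real_
  )
}

#' Write / read the per-species intron table
#'
#' TSV with one row per gene: `gene_id`, `bpi`, `gci`, `n_introns`.
#'
#' @param ds A [species_dataset()].
#' @param path Output file.
#' @return `write_intron_table()` returns `path` invisibly;
#'   `read_intron_table()` returns a tibble.
#' @export
write_intron_table <- function(ds, path) {
  stopifnot(inherits(ds, "species_dataset"))
  readr::write_tsv(ds$introns[, c("gene_id", "bpi", "gci", "n_introns")], path)
  invisible(path)
}

#' @rdname write_intron_table
#' @export
read_intron_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(gene_id = "c", bpi = "i",
                                          gci = "d", n_introns = "i"))
}
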