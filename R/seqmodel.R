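# Sequence-level primitives: base composition, QC flags, gene models and
# internal-intron extraction. Coordinates are 1-based closed throughout
# (the IRanges convention); GFF3 I/O matches this directly.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' GC content of nucleotide sequences
#'
#' GC percent computed as the molar ratio of guanine plus cytosine over all
#' unambiguous bases, `100 * (G + C) / (A + C + G + T)`. Counting is
#' case-insensitive, so soft-masked (lowercase) bases contribute like their
#' uppercase counterparts unless `exclude_soft = TRUE`; hard-masked `N` and
#' any other ambiguity codes are excluded from numerator and denominator.
#'
#' @param sequence Character vector of nucleotide sequences.
#' @param exclude_soft If `TRUE`, lowercase (soft-masked) bases are excluded
#'   from both counts instead of being counted as bases.
#' @return Numeric vector of GC percentages in `[0, 100]`.
#' @examples
#' gc_content(c("GCAT", "GGCC", "GCATNN"))
#' @export
gc_content <- function(sequence, exclude_soft = FALSE) {
  stopifnot(is.character(sequence))
  if (exclude_soft) {
    gc <- stringr::str_count(sequence, "[GC]")
    at <- stringr::str_count(sequence, "[AT]")
  } else {
    gc <- stringr::str_count(sequence, "[GCgc]")
    at <- stringr::str_count(sequence, "[ATat]")
  }
  tot <- gc + at
  if (any(tot == 0L)) {
    abort("gc_content() is undefined for sequences with no unambiguous bases.",
          class = "introdelta_undefined_value")
  }
  100 * gc / tot
}

# NA-safe variant used for bookkeeping tables (empty intronic sequences).
gc_or_na <- function(sequence) {
  gc <- stringr::str_count(sequence, "[GCgc]")
  at <- stringr::str_count(sequence, "[ATat]")
  tot <- gc + at
  ifelse(tot == 0L, NA_real_, 100 * gc / tot)
}

#' Flag sequences containing base ambiguity
#'
#' `TRUE` for any sequence holding a character outside `A`, `C`, `G`, `T`
#' (case-insensitive). `N` counts as ambiguity: raw-input QC discards such
#' sequences before analysis.
#'
#' @param sequence Character vector of nucleotide sequences.
#' @return Logical vector.
#' @examples
#' has_base_ambiguity(c("ACGT", "ACRT", "ACNT"))
#' @export
has_base_ambiguity <- function(sequence) {
  stopifnot(is.character(sequence))
  stringr::str_detect(sequence, "[^ACGTacgt]")
}

#' Flag coding sequences with an internal stop codon
#'
#' Scans the reading frame (frame 0, standard genetic code) and reports
#' whether any codon before the terminal one is a stop. Sequences whose
#' length is not a multiple of three cannot be framed and are flagged as
#' malformed with `NA`; such CDS are removed from orthology input.
#'
#' @param cds Character vector of coding sequences.
#' @return Logical vector; `NA` marks a malformed CDS.
#' @examples
#' has_internal_stop(c("ATGAAATAG", "ATGTAAAAATAG", "ATGAA"))
#' @export
has_internal_stop <- function(cds) {
  stopifnot(is.character(cds))
  vapply(toupper(cds), function(s) {
    n <- nchar(s)
    if (n %% 3L != 0L || n == 0L) return(NA)
    if (n < 6L) return(FALSE)
    starts <- seq.int(1L, n - 5L, by = 3L)
    any(substring(s, starts, starts + 2L) %in% STOP_CODONS)
  }, logical(1), USE.NAMES = FALSE)
}

revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(sequence)))
}

#' Construct a gene model
#'
#' A gene model ties one gene's exon and CDS intervals (1-based closed, on
#' genomic coordinates of a single contig) to its source sequence. Exons
#' must be non-overlapping and sorted; CDS intervals must lie within the
#' exon footprint.
#'
#' @param gene_id,species_id Identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exon_intervals,cds_intervals Two-column matrices (start, end).
#' @param seq Contig sequence as a single character string (or `DNAString`).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, species_id, strand, exon_intervals,
                       cds_intervals, seq) {
  strand <- as.character(strand)
  stopifnot(strand %in% c("+", "-"))
  exon_intervals <- as_interval_matrix(exon_intervals)
  cds_intervals <- as_interval_matrix(cds_intervals)
  if (nrow(exon_intervals) < 1L) {
    abort("A gene model needs at least one exon.")
  }
  if (is.unsorted(exon_intervals[, 1L]) ||
      any(diff(as.vector(t(exon_intervals))) < 0)) {
    abort("Exon intervals must be sorted and non-overlapping.")
  }
  if (any(exon_intervals[, 2L] < exon_intervals[, 1L])) {
    abort("Exon intervals must satisfy start <= end.")
  }
  seq <- as.character(seq)
  if (any(exon_intervals[, 2L] > nchar(seq)) || any(exon_intervals[, 1L] < 1L)) {
    abort("Exon interval outside contig bounds.",
          class = "introdelta_coordinate_error")
  }
  if (nrow(cds_intervals) > 0L) {
    inside <- vapply(seq_len(nrow(cds_intervals)), function(i) {
      any(cds_intervals[i, 1L] >= exon_intervals[, 1L] &
            cds_intervals[i, 2L] <= exon_intervals[, 2L])
    }, logical(1))
    if (!all(inside)) {
      abort("CDS intervals must lie within the exon footprint.",
            class = "introdelta_coordinate_error")
    }
  }
  structure(
    list(gene_id = gene_id, species_id = species_id, strand = strand,
         exon_intervals = exon_intervals, cds_intervals = cds_intervals,
         seq = seq),
    class = "gene_model"
  )
}

as_interval_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
  if (is.null(x) || length(x) == 0L) {
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  x <- matrix(as.integer(x), ncol = 2L)
  colnames(x) <- c("start", "end")
  x[order(x[, 1L]), , drop = FALSE]
}

#' Extract and concatenate a gene's internal introns
#'
#' Introns are the gaps between consecutive exons. Only *internal* introns
#' are retained: those lying strictly between the first and last
#' CDS-containing exons of the transcript. Introns entirely within the 5'
#' or 3' UTR ("flanking" introns) are discarded. With
#' `internal_rule = "trim_terminal"` the alternative reading is applied:
#' the first and last intron of the transcript are dropped regardless of
#' the CDS span. Sequences are returned in transcription order, reverse
#' complemented for minus-strand genes, and concatenated.
#'
#' @param gene A [gene_model()].
#' @param internal_rule `"cds_span"` (default) or `"trim_terminal"`.
#' @return One-row tibble with `gene_id`, `species_id`, `sequence`, `bpi`
#'   (intronic length), `gci` (GC percent, `NA` if no internal introns) and
#'   `n_introns`. A gene without internal introns yields an empty sequence
#'   (excluded downstream).
#' @export
extract_internal_introns <- function(gene, internal_rule = c("cds_span", "trim_terminal")) {
  stopifnot(inherits(gene, "gene_model"))
  internal_rule <- arg_match(internal_rule)
  ex <- gene$exon_intervals
  n_ex <- nrow(ex)
  keep <- logical(max(n_ex - 1L, 0L))
  if (n_ex >= 2L) {
    if (internal_rule == "cds_span") {
      cds <- gene$cds_intervals
      if (nrow(cds) > 0L) {
        cds_exon <- which(vapply(seq_len(n_ex), function(i) {
          any(cds[, 1L] <= ex[i, 2L] & cds[, 2L] >= ex[i, 1L])
        }, logical(1)))
        if (length(cds_exon) > 0L) {
          lo <- min(cds_exon); hi <- max(cds_exon)
          if (hi > lo) keep[lo:(hi - 1L)] <- TRUE
        }
      }
    } else {
      if (n_ex > 3L) keep[2L:(n_ex - 2L)] <- TRUE
      if (n_ex == 3L) keep[2L] <- FALSE  # both introns are terminal
    }
  }
  idx <- which(keep)
  seqs <- vapply(idx, function(i) {
    substr(gene$seq, ex[i, 2L] + 1L, ex[i + 1L, 1L] - 1L)
  }, character(1))
  seqs <- seqs[nchar(seqs) > 0L]
  if (gene$strand == "-") seqs <- rev(revcomp(seqs))
  concat <- paste(seqs, collapse = "")
  tibble(
    gene_id = gene$gene_id,
    species_id = gene$species_id,
    sequence = concat,
    bpi = nchar(concat),
    gci = gc_or_na(concat),
    n_introns = length(seqs)
  )
}
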