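# Repeat masking of intronic sequences: a built-in exact-substring library
# matcher (both strands, k-mer seeded) plus an importer for external masks,
# and the removed-fraction statistics computed over masked cohorts.

#' Build or read a repeat library
#'
#' A repeat library is a set of named consensus sequences (A/C/G/T only)
#' representing interspersed repeats to be masked.
#'
#' @param elements Named character vector of consensus sequences.
#' @return Object of class `repeat_library`.
#' @export
repeat_library <- function(elements) {
  stopifnot(is.character(elements), !is.null(names(elements)))
  if (any(nchar(elements) == 0L) || any(has_base_ambiguity(elements))) {
    abort("Repeat consensus sequences must be non-empty and A/C/G/T only.")
  }
  structure(list(elements = toupper(elements)), class = "repeat_library")
}

#' @rdname repeat_library
#' @param path FASTA file of consensus sequences.
#' @export
read_repeat_library <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  repeat_library(setNames(as.character(x), sub("\\s.*$", "", names(x))))
}

#' Mask intronic sequences with a repeat library
#'
#' Every exact occurrence, on either strand, of a library-consensus
#' substring of length >= `min_match` is hard-masked to `N` (matches are
#' seeded with `min_match`-mers of the consensus and merged, so partial
#' element copies are caught). Single-base runs of length >=
#' `low_complexity_run` are masked as low-complexity. Masking is
#' idempotent. No alignment-level fidelity to heuristic repeat finders is
#' claimed; [import_external_mask()] is the high-fidelity path for masks
#' produced by dedicated tools.
#'
#' @param introns Tibble with at least `gene_id` and `sequence` (e.g. the
#'   `introns` table of a [species_dataset()]).
#' @param lib A [repeat_library()].
#' @param min_match Minimum exact match length in bases (>= 10).
#' @param low_complexity_run Minimum single-base run length to mask;
#'   `Inf` disables low-complexity masking.
#' @return A mask-result tibble: `gene_id`, `masked_intervals` (list column
#'   of tibbles `start`,`end`, 1-based closed), `masked_bp`, `masked_gc`
#'   (GC percent of masked bases, `NA` when nothing is masked),
#'   `masked_sequence`, `bpi_before`, `gci_before`, `bpi_after`,
#'   `gci_after`. "After" values exclude masked bases.
#' @export
mask_with_library <- function(introns, lib, min_match = 15,
                              low_complexity_run = 20) {
  stopifnot(inherits(lib, "repeat_library"), min_match >= 10)
  seqs <- toupper(introns$sequence)
  k <- as.integer(min_match)
  kmers <- unique(unlist(lapply(c(lib$elements, revcomp(lib$elements)),
                                function(e) {
    n <- nchar(e)
    if (n < k) return(character())
    substring(e, 1:(n - k + 1L), k:n)
  })))
  pdict <- if (length(kmers)) Biostrings::PDict(Biostrings::DNAStringSet(kmers)) else NULL
  dna <- Biostrings::DNAStringSet(seqs)
  iv_list <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    hits <- IRanges::IRanges()
    if (!is.null(pdict) && nchar(seqs[i]) >= k) {
      m <- Biostrings::matchPDict(pdict, dna[[i]])
      hits <- unlist(IRanges::IRangesList(m))
    }
    if (is.finite(low_complexity_run)) {
      hits <- c(hits, low_complexity_runs(seqs[i], low_complexity_run))
    }
    iv_list[[i]] <- IRanges::reduce(hits)
  }
  finish_mask(introns, seqs, iv_list)
}

low_complexity_runs <- function(seq, min_run) {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= min_run & r$values %in% c("A", "C", "G", "T")
  IRanges::IRanges(start = (ends - r$lengths + 1L)[keep], end = ends[keep])
}

finish_mask <- function(introns, seqs, iv_list) {
  n <- length(seqs)
  masked_bp <- integer(n); masked_gc <- numeric(n)
  masked_sequence <- character(n); gci_after <- numeric(n)
  ivs <- vector("list", n)
  for (i in seq_len(n)) {
    iv <- iv_list[[i]]
    s <- seqs[i]
    if (length(iv) > 0L) {
      if (min(IRanges::start(iv)) < 1L || max(IRanges::end(iv)) > nchar(s)) {
        abort("Mask interval outside sequence bounds.",
              class = "introdelta_coordinate_error")
      }
      masked_chunk <- paste(substring(s, IRanges::start(iv), IRanges::end(iv)),
                            collapse = "")
      ms <- s
      for (j in seq_along(iv)) {
        st <- IRanges::start(iv)[j]; en <- IRanges::end(iv)[j]
        substr(ms, st, en) <- strrep("N", en - st + 1L)
      }
      masked_bp[i] <- sum(IRanges::width(iv))
      masked_gc[i] <- gc_or_na(masked_chunk)
      masked_sequence[i] <- ms
      gci_after[i] <- gc_or_na(ms)
    } else {
      masked_bp[i] <- 0L
      masked_gc[i] <- NA_real_
      masked_sequence[i] <- s
      gci_after[i] <- gc_or_na(s)
    }
    ivs[[i]] <- tibble(start = IRanges::start(iv), end = IRanges::end(iv))
  }
  tibble(
    gene_id = introns$gene_id,
    masked_intervals = ivs,
    masked_bp = masked_bp,
    masked_gc = masked_gc,
    masked_sequence = masked_sequence,
    bpi_before = nchar(seqs),
    gci_before = gc_or_na(seqs),
    bpi_after = nchar(seqs) - masked_bp,
    gci_after = gci_after
  )
}

#' Import an external repeat mask
#'
#' Applies a mask produced by an external tool, supplied either as a
#' 3-column interval TSV (`seq_id`, `start`, `end`; 0-based half-open, the
#' conventional interval-file encoding) or as a soft-masked FASTA whose
#' lowercase letters mark repeats.
#'
#' @param introns Tibble with `gene_id` and `sequence`.
#' @param intervals Path to an interval TSV, or a tibble with columns
#'   `seq_id`, `start`, `end` (0-based half-open).
#' @param softmasked_fasta Path to a soft-masked FASTA keyed by gene id
#'   (alternative to `intervals`).
#' @return Mask-result tibble as in [mask_with_library()].
#' @export
import_external_mask <- function(introns, intervals = NULL,
                                 softmasked_fasta = NULL) {
  seqs <- toupper(introns$sequence)
  n <- length(seqs)
  iv_list <- rep(list(IRanges::IRanges()), n)
  if (!is.null(intervals)) {
    if (is.character(intervals)) {
      intervals <- readr::read_tsv(
        intervals, col_names = c("seq_id", "start", "end"),
        col_types = readr::cols("c", "i", "i"))
    }
    idx <- match(intervals$seq_id, introns$gene_id)
    if (anyNA(idx)) {
      abort("Mask interval references an unknown sequence id.",
            class = "introdelta_lookup_error")
    }
    for (i in seq_len(n)) {
      sel <- which(idx == i)
      if (length(sel)) {
        st <- intervals$start[sel] + 1L  # to 1-based closed
        en <- intervals$end[sel]
        if (any(st < 1L) || any(en > nchar(seqs[i])) || any(en < st)) {
          abort("Mask interval outside sequence bounds.",
                class = "introdelta_coordinate_error")
        }
        iv_list[[i]] <- IRanges::reduce(IRanges::IRanges(start = st, end = en))
      }
    }
  } else if (!is.null(softmasked_fasta)) {
    sm <- Biostrings::readBStringSet(softmasked_fasta)
    names(sm) <- sub("\\s.*$", "", names(sm))
    idx <- match(introns$gene_id, names(sm))
    if (anyNA(idx)) {
      abort("Soft-masked FASTA is missing sequences.",
            class = "introdelta_lookup_error")
    }
    for (i in seq_len(n)) {
      s <- as.character(sm[[idx[i]]])
      if (nchar(s) != nchar(seqs[i])) {
        abort("Soft-masked sequence length differs from the intronic sequence.",
              class = "introdelta_coordinate_error")
      }
      lower <- gregexpr("[acgtn]+", s)[[1]]
      if (lower[1] != -1L) {
        iv_list[[i]] <- IRanges::IRanges(
          start = as.integer(lower),
          width = attr(lower, "match.length"))
      }
    }
  } else {
    abort("Provide either `intervals` or `softmasked_fasta`.")
  }
  finish_mask(introns, seqs, iv_list)
}

#' Export mask intervals
#'
#' Writes the masked intervals of a mask result as a 3-column TSV
#' (`seq_id`, `start`, `end`; 0-based half-open), re-importable via
#' [import_external_mask()].
#'
#' @param mask Mask-result tibble.
#' @param path Output file.
#' @export
export_mask_intervals <- function(mask, path) {
  iv <- mask |>
    select("gene_id", "masked_intervals") |>
    tidyr::unnest("masked_intervals") |>
    transmute(seq_id = .data$gene_id, start = .data$start - 1L, end = .data$end)
  readr::write_tsv(iv, path, col_names = FALSE)
  invisible(path)
}

#' Removed-fraction statistics of a masked cohort
#'
#' Per-sequence masked length percent (`100 * masked_bp / bpi_before`) and
#' GC percent of the masked bases, averaged across sequences with their
#' standard errors — the per-species summary of what repeat masking
#' removed. Sequences with nothing masked contribute 0 to the bp%% average
#' and are excluded from the masked-GC average (reported `NA` if no
#' sequence has masked bases).
#'
#' @param mask Mask-result tibble from [mask_with_library()] or
#'   [import_external_mask()].
#' @return One-row tibble: `n`, `mean_bp_pct`, `se_bp_pct`,
#'   `mean_masked_gc`, `se_masked_gc`.
#' @export
mask_stats <- function(mask) {
  stopifnot(nrow(mask) >= 1L)
  bp_pct <- 100 * mask$masked_bp / mask$bpi_before
  gc_vals <- mask$masked_gc[mask$masked_bp > 0]
  se <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else 0
  tibble(
    n = nrow(mask),
    mean_bp_pct = mean(bp_pct),
    se_bp_pct = se(bp_pct),
    mean_masked_gc = if (length(gc_vals)) mean(gc_vals) else NA_real_,
    se_masked_gc = if (length(gc_vals)) se(gc_vals) else NA_real_
  )
}

#' Apply a mask result back onto an intron table
#'
#' Returns the intron table re-measured after masking: `sequence` is the
#' hard-masked sequence, `bpi` excludes masked bases and `gci` is the GC of
#' the unmasked bases only.
#'
#' @param introns Intron tibble (as in a [species_dataset()]).
#' @param mask Matching mask-result tibble.
#' @return Intron tibble with updated `sequence`, `bpi`, `gci`.
#' @export
apply_mask <- function(introns, mask) {
  idx <- match(introns$gene_id, mask$gene_id)
  if (anyNA(idx)) abort("Mask result does not cover every intron.",
                        class = "introdelta_lookup_error")
  introns$sequence <- mask$masked_sequence[idx]
  introns$bpi <- mask$bpi_after[idx]
  introns$gci <- mask$gci_after[idx]
  introns
}
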