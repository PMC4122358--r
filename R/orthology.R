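# Reciprocal-best-hit (RBH) orthology on protein sequences, and extension
# of CDS orthology to the concatenated internal-intron sequences.

#' All-vs-all protein similarity hits
#'
#' Scores every query against every subject and returns ranked hits. The
#' built-in scorer is Smith-Waterman local alignment with BLOSUM62 scoring
#' and affine gaps (open 11, extend 1); it reports raw scores only, so the
#' retained-hit floor is a raw-score threshold (`score_min`). E-values are
#' carried (and thresholded) only for hits imported from an external
#' aligner via [import_tabular_hits()].
#'
#' @param proteins_a,proteins_b Named character vectors of protein
#'   sequences (queries and subjects). Inputs should have passed CDS QC.
#' @param score_min Minimum raw alignment score for a hit to be retained.
#' @param scorer Optional function `(proteins_a, proteins_b)` returning a
#'   numeric matrix of scores (rows = queries, cols = subjects), replacing
#'   the built-in aligner.
#' @return Tibble of hits: `query_id`, `subject_id`, `score`, `evalue`
#'   (`NA` for the built-in scorer), ranked by descending score per query.
#' @export
all_vs_all_hits <- function(proteins_a, proteins_b, score_min = 50,
                            scorer = NULL) {
  if (length(proteins_a) == 0L || length(proteins_b) == 0L) {
    warn("Empty protein set: no hits.")
    return(tibble(query_id = character(), subject_id = character(),
                  score = numeric(), evalue = numeric()))
  }
  stopifnot(!is.null(names(proteins_a)), !is.null(names(proteins_b)))
  scorer <- scorer %||% blosum62_local_scores
  scores <- scorer(proteins_a, proteins_b)
  stopifnot(nrow(scores) == length(proteins_a),
            ncol(scores) == length(proteins_b))
  hits <- tibble(
    query_id = rep(names(proteins_a), times = length(proteins_b)),
    subject_id = rep(names(proteins_b), each = length(proteins_a)),
    score = as.vector(scores),
    evalue = NA_real_
  ) |>
    filter(.data$score >= score_min) |>
    arrange(.data$query_id, desc(.data$score))
  hits
}

blosum62_local_scores <- function(proteins_a, proteins_b) {
  pa <- Biostrings::AAStringSet(proteins_a)
  pb <- Biostrings::AAStringSet(proteins_b)
  out <- matrix(0, nrow = length(pa), ncol = length(pb))
  for (j in seq_along(pb)) {
    out[, j] <- Biostrings::pairwiseAlignment(
      pattern = pa, subject = pb[[j]], type = "local",
      substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE
    )
  }
  out
}

#' Reciprocal best hits
#'
#' A pair `(a, b)` is retained iff `b` is `a`'s unique top-scoring hit in
#' the A-to-B table and `a` is `b`'s unique top-scoring hit in B-to-A, with
#' both hits passing the e-value threshold where e-values are available.
#' Ties for best hit drop the gene from pairing, preserving the one-to-one
#' guarantee.
#'
#' @param hits_ab,hits_ba Hit tibbles from [all_vs_all_hits()] or
#'   [import_tabular_hits()], in the two directions.
#' @param evalue_max Maximum e-value for hits that carry one (default
#'   `1e-10`); hits with `NA` e-values (built-in scorer) are not
#'   e-value-filtered.
#' @param species_m,species_z Labels stored on the output.
#' @return Tibble of ortholog pairs: `species_m`, `gene_m`, `species_z`,
#'   `gene_z`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, evalue_max = 1e-10,
                                 species_m = "m", species_z = "z") {
  best_ab <- unique_best(filter_evalue(hits_ab, evalue_max))
  best_ba <- unique_best(filter_evalue(hits_ba, evalue_max))
  pairs <- inner_join(
    best_ab, best_ba,
    by = c(query_id = "subject_id", subject_id = "query_id")
  )
  tibble(species_m = species_m, gene_m = pairs$query_id,
         species_z = species_z, gene_z = pairs$subject_id) |>
    arrange(.data$gene_m)
}

filter_evalue <- function(hits, evalue_max) {
  filter(hits, is.na(.data$evalue) | .data$evalue <= evalue_max)
}

# unique argmax per query; ties for the top score drop the query
unique_best <- function(hits) {
  if (nrow(hits) == 0L) {
    return(tibble(query_id = character(), subject_id = character()))
  }
  hits |>
    group_by(.data$query_id) |>
    filter(.data$score == max(.data$score)) |>
    filter(n() == 1L) |>
    ungroup() |>
    select("query_id", "subject_id")
}

#' Import / export 12-column tabular similarity hits
#'
#' The conventional tab-separated hit format: query, subject, percent
#' identity, alignment length, mismatches, gap opens, qstart, qend, sstart,
#' send, evalue, bitscore. Bitscore is used as the hit score.
#'
#' @param path File path.
#' @return Tibble of hits (`query_id`, `subject_id`, `score`, `evalue`,
#'   plus the remaining columns).
#' @export
import_tabular_hits <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- stringr::str_split(lines, "\t")
  bad <- which(lengths(fields) != 12L)
  if (length(bad) > 0L) {
    abort(sprintf("Malformed hit row at line %d: expected 12 tab-separated columns, found %d.",
                  bad[1], length(fields[[bad[1]]])),
          class = "introdelta_format_error")
  }
  m <- do.call(rbind, fields)
  tibble(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = as.numeric(m[, 3]), length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), score = as.numeric(m[, 12])
  )
}

#' @rdname import_tabular_hits
#' @param hits Hit tibble; missing tabular columns are filled with zeros.
#' @export
export_tabular_hits <- function(hits, path) {
  defaults <- tibble(
    pct_identity = 0, length = 0L, mismatches = 0L, gap_opens = 0L,
    qstart = 0L, qend = 0L, sstart = 0L, send = 0L
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(hits)) hits[[nm]] <- defaults[[nm]]
  }
  if (!"evalue" %in% names(hits)) hits$evalue <- NA_real_
  out <- hits[, c("query_id", "subject_id", "pct_identity", "length",
                  "mismatches", "gap_opens", "qstart", "qend", "sstart",
                  "send", "evalue", "score")]
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Extend CDS orthology to intronic sequences
#'
#' Maps each CDS ortholog pair to the two species' concatenated
#' internal-intron records. Pairs where either member has an empty
#' intronic sequence are dropped; the count of dropped pairs is reported
#' via a message and the `n_dropped` attribute.
#'
#' @param pairs Ortholog pair tibble from [reciprocal_best_hits()].
#' @param ds_m,ds_z The two [species_dataset()]s, in pair orientation.
#' @return Tibble of intron pairs: `gene_m`, `gene_z`, `sequence_m`,
#'   `bpi_m`, `gci_m`, `sequence_z`, `bpi_z`, `gci_z`.
#' @export
extend_to_introns <- function(pairs, ds_m, ds_z) {
  stopifnot(inherits(ds_m, "species_dataset"), inherits(ds_z, "species_dataset"))
  missing_m <- setdiff(pairs$gene_m, ds_m$genes$gene_id)
  missing_z <- setdiff(pairs$gene_z, ds_z$genes$gene_id)
  if (length(missing_m) || length(missing_z)) {
    abort(sprintf("Ortholog pairs reference unknown genes (e.g. '%s').",
                  c(missing_m, missing_z)[1]),
          class = "introdelta_lookup_error")
  }
  im <- ds_m$introns |>
    select(gene_m = "gene_id", sequence_m = "sequence",
           bpi_m = "bpi", gci_m = "gci")
  iz <- ds_z$introns |>
    select(gene_z = "gene_id", sequence_z = "sequence",
           bpi_z = "bpi", gci_z = "gci")
  joined <- pairs |>
    select("gene_m", "gene_z") |>
    left_join(im, by = "gene_m") |>
    left_join(iz, by = "gene_z")
  ok <- !is.na(joined$bpi_m) & joined$bpi_m > 0 &
    !is.na(joined$bpi_z) & joined$bpi_z > 0
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    inform(sprintf("Dropped %d ortholog pair(s) lacking internal introns in at least one species.",
                   n_dropped))
  }
  out <- joined[ok, ]
  attr(out, "n_dropped") <- n_dropped
  out
}
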