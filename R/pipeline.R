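# End-to-end orchestration: every unordered species pair, both masking
# variants, plus the species-level and cross-comparison statistics.

#' Run the comparative intron pipeline
#'
#' For every unordered pair of species (ordered by `phylo_order`; the
#' species appearing later is the "first" species m of the delta, so
#' comparisons group by the earlier species as cluster anchor), computes
#' delta records before and (when a repeat library or masks are given)
#' after repeat masking, applies the negligible-delta filter, the
#' percent-positive summary, the four-class frequencies and the exact
#' binomial test of the dominant class, with BH adjustment across the
#' whole comparison-by-variant family.
#'
#' @param datasets Named list of [species_dataset()]s (>= 2).
#' @param pairs Ortholog pairs: `"rbh"` to infer them with the built-in
#'   aligner ([all_vs_all_hits()] + [reciprocal_best_hits()] on QC-passing
#'   proteins), or a named list of pair tibbles (`gene_m`, `gene_z`) keyed
#'   by `"<m>|<z>"` comparison labels (e.g. the generator truth pairing).
#' @param lib Optional [repeat_library()]; enables the "after" masking
#'   variant.
#' @param phylo_order Species ids in phylogenetic order; defaults to the
#'   order of `datasets`.
#' @param mr_records Optional per-specimen MR tibble (from
#'   [summarize_mr()]`$records`) for the cross-comparison correlation and
#'   SNK stages.
#' @param gc_threshold,bp_threshold,filter_rule Passed to
#'   [filter_deltas()].
#' @param null_p,null Passed to [binomial_test_top_class()].
#' @param score_min Passed to [all_vs_all_hits()] when `pairs = "rbh"`.
#' @return List of result tables: `species_summary`, `mask_stats`,
#'   `pairwise`, `class_freqs`, `binomial`, `removed`, `spearman`, `snk`,
#'   `config`.
#' @export
run_pipeline <- function(datasets, pairs = "rbh", lib = NULL,
                         phylo_order = names(datasets), mr_records = NULL,
                         gc_threshold = 0.1, bp_threshold = 100,
                         filter_rule = "or", null_p = 0.25,
                         null = "uniform", score_min = 50) {
  stopifnot(length(datasets) >= 2L, !is.null(names(datasets)))
  if (!setequal(phylo_order, names(datasets))) {
    abort("phylo_order must be a permutation of the dataset names.")
  }
  datasets <- datasets[phylo_order]
  sp <- phylo_order
  combos <- utils::combn(length(sp), 2L)

  masks <- NULL
  if (!is.null(lib)) {
    masks <- lapply(datasets, function(ds) mask_with_library(ds$introns, lib))
  }

  pairwise <- list(); class_freqs <- list(); binomial <- list()
  removed <- list()
  for (ci in seq_len(ncol(combos))) {
    z_id <- sp[combos[1L, ci]]  # earlier in phylogenetic order: subtracted
    m_id <- sp[combos[2L, ci]]
    label <- paste0(m_id, "|", z_id)
    ds_m <- datasets[[m_id]]; ds_z <- datasets[[z_id]]

    pr <- resolve_pairs(pairs, label, ds_m, ds_z, score_min)
    intron_pairs <- extend_to_introns(pr, ds_m, ds_z)

    variants <- list(before = intron_pairs)
    if (!is.null(masks)) {
      after <- intron_pairs
      mm <- masks[[m_id]]; mz <- masks[[z_id]]
      im <- match(after$gene_m, mm$gene_id)
      iz <- match(after$gene_z, mz$gene_id)
      after$bpi_m <- mm$bpi_after[im]; after$gci_m <- mm$gci_after[im]
      after$bpi_z <- mz$bpi_after[iz]; after$gci_z <- mz$gci_after[iz]
      ok <- after$bpi_m > 0 & after$bpi_z > 0 &
        !is.na(after$gci_m) & !is.na(after$gci_z)
      variants$after <- after[ok, ]
    }
    for (v in names(variants)) {
      deltas <- compute_deltas(variants[[v]], species = c(m_id, z_id),
                               masked_variant = v)
      kept <- filter_deltas(deltas, gc_threshold, bp_threshold,
                            rule = filter_rule)
      key <- paste0(label, ":", v)
      removed[[key]] <- tibble(
        comparison = label, masked_variant = v,
        n_input = nrow(deltas), n_removed = attr(kept, "n_removed"),
        removed_fraction = removed_fraction(kept))
      if (nrow(kept) == 0L) next
      cls <- classify_deltas(kept)
      freq <- class_frequencies(cls, comparison = key)
      pairwise[[key]] <- pairwise_summary(kept, comparison = label) |>
        mutate(masked_variant = v, .after = "comparison")
      class_freqs[[key]] <- tidy(freq) |> mutate(masked_variant = v)
      binomial[[key]] <- binomial_test_top_class(freq, null_p = null_p,
                                                 null = null) |>
        mutate(comparison = label, masked_variant = v, .before = 1)
    }
  }
  binomial_tbl <- list_rbind(binomial)
  if (nrow(binomial_tbl)) {
    binomial_tbl$p_adjusted <- adjust_fdr(binomial_tbl$p_value)
  }

  species_summary <- list_rbind(map(datasets, dataset_summary))
  mask_tbl <- if (!is.null(masks)) {
    list_rbind(imap(masks, function(mk, id) {
      mask_stats(mk) |> mutate(species_id = id, .before = 1)
    }))
  } else {
    tibble()
  }

  pairwise_tbl <- list_rbind(pairwise)
  spearman_tbl <- cross_comparison_spearman(pairwise_tbl, mr_records)
  snk_res <- if (!is.null(mr_records)) {
    snk_test(as.data.frame(mr_records), value = "mr", group = "species_id")
  } else {
    NULL
  }

  list(
    species_summary = species_summary,
    mask_stats = mask_tbl,
    pairwise = pairwise_tbl,
    class_freqs = list_rbind(class_freqs),
    binomial = binomial_tbl,
    removed = list_rbind(removed),
    spearman = spearman_tbl,
    snk = snk_res,
    config = list(phylo_order = sp, gc_threshold = gc_threshold,
                  bp_threshold = bp_threshold, filter_rule = filter_rule,
                  null_p = null_p, null = null,
                  masking = !is.null(lib))
  )
}

resolve_pairs <- function(pairs, label, ds_m, ds_z, score_min) {
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pr <- pairs[[label]]
    if (is.null(pr)) abort(sprintf("No ortholog pairs supplied for '%s'.", label))
    return(pr)
  }
  if (identical(pairs, "rbh")) {
    pm <- ds_m$protein_seqs[qc_pass_genes(ds_m)]
    pz <- ds_z$protein_seqs[qc_pass_genes(ds_z)]
    hits_mz <- all_vs_all_hits(pm, pz, score_min = score_min)
    hits_zm <- all_vs_all_hits(pz, pm, score_min = score_min)
    return(reciprocal_best_hits(hits_mz, hits_zm,
                                species_m = ds_m$species_id,
                                species_z = ds_z$species_id))
  }
  abort("`pairs` must be \"rbh\" or a named list of pair tibbles.")
}

# Spearman correlations among mean delta bpi, delta GCi (before masking)
# and, when MR records are given, delta MR across comparisons.
cross_comparison_spearman <- function(pairwise_tbl, mr_records) {
  if (is.null(pairwise_tbl) || nrow(pairwise_tbl) == 0L) return(tibble())
  before <- pairwise_tbl |> filter(.data$masked_variant == "before")
  if (nrow(before) < 4L) return(tibble())
  vars <- list(delta_bpi = before$mean_delta_bpi,
               delta_gci = before$mean_delta_gci)
  if (!is.null(mr_records)) {
    mr_mean <- mr_records |>
      filter(.data$valid) |>
      group_by(.data$species_id) |>
      summarise(mr = mean(.data$mr), .groups = "drop")
    mz <- stringr::str_split_fixed(before$comparison, stringr::fixed("|"), 2)
    d_mr <- mr_mean$mr[match(mz[, 1], mr_mean$species_id)] -
      mr_mean$mr[match(mz[, 2], mr_mean$species_id)]
    if (!anyNA(d_mr)) vars$delta_mr <- d_mr
  }
  nm <- names(vars)
  out <- list()
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (i >= j) next
      ct <- spearman_cor(vars[[i]], vars[[j]])
      out[[paste(nm[i], nm[j])]] <- tibble(
        var_1 = nm[i], var_2 = nm[j], rho = ct$rho,
        p_value = ct$p_value, n = ct$n)
    }
  }
  list_rbind(out)
}

#' Simulate a respirometry study for a set of species
#'
#' Draws per-specimen mass-specific rates from per-species lognormal
#' distributions, converts them into whole-animal rates and emits seeded
#' noisy traces, recording the truth.
#'
#' @param cfg A [synth_config()] (uses `mr_meanlog`, `mr_sdlog`,
#'   `trace_noise_frac`, `seed`).
#' @param species_ids Species labels, matched positionally against the
#'   names of `cfg$mr_meanlog`.
#' @param n_specimens Specimens per species.
#' @param temp_c Measurement temperatures per species (recycled).
#' @param mass_kg Specimen mass, kg.
#' @return List `traces` (list of [respirometry_trace()]) and `truth`
#'   (tibble: `species_id`, `specimen`, `true_mr0`, `true_rate_ug_h`,
#'   `temp_c`).
#' @export
generate_mr_study <- function(cfg, species_ids = c("species_m", "species_z"),
                              n_specimens = 8, temp_c = 26,
                              mass_kg = 0.005) {
  stopifnot(inherits(cfg, "synth_config"))
  temp_c <- rep_len(temp_c, length(species_ids))
  withr::with_seed(cfg$seed + 1L, {
    traces <- list(); rows <- list()
    for (s in seq_along(species_ids)) {
      meanlog <- cfg$mr_meanlog[min(s, length(cfg$mr_meanlog))]
      sdlog <- cfg$mr_sdlog[min(s, length(cfg$mr_sdlog))]
      mr0 <- rlnorm(n_specimens, meanlog, sdlog)  # mgO2/kg/h
      for (i in seq_len(n_specimens)) {
        rate_ug_h <- mr0[i] * 1000 * mass_kg
        tr <- generate_trace(rate_ug_h,
                             noise_frac = cfg$trace_noise_frac,
                             temp_c = temp_c[s], mass_kg = mass_kg,
                             species_id = species_ids[s],
                             seed = sample.int(2^30, 1L))
        traces[[length(traces) + 1L]] <- tr
        rows[[length(rows) + 1L]] <- tibble(
          species_id = species_ids[s], specimen = i, true_mr0 = mr0[i],
          true_rate_ug_h = rate_ug_h, temp_c = temp_c[s])
      }
    }
    list(traces = traces, truth = list_rbind(rows))
  })
}
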