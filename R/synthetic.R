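# Seeded synthetic-data generators. They emulate the statistical structure
# the comparative analysis consumes -- two-species ortholog sets with
# controlled (delta bpi, delta GCi) sign-class structure, skewed intronic
# GC distributions, repeat insertions of known GC, and noisy linear
# oxygen-depletion traces -- and record the generating truth so every
# downstream stage can be scored.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Synthetic-study configuration
#'
#' Generating parameters for a two-species ortholog set. Defaults describe
#' the study conditions the package's recovery tests run under: a dominant
#' shorter-and-GC-richer class (N/P 60%), a rare opposite class (P/N 5%),
#' a 5% sub-threshold fraction, skewed intronic GC around 40% and
#' heavy-tailed lognormal intron lengths.
#'
#' @param seed Integer seed; identical seed and config give byte-identical
#'   output.
#' @param n_genes Number of ortholog pairs.
#' @param class_probs Probabilities of the four sign classes
#'   (N/P, N/N, P/N, P/P); must sum to 1.
#' @param gci_mean,gci_sd,gci_shape Skew-normal parameters of the first
#'   species' intronic GC (percent), truncated to (0, 100).
#' @param bpi_meanlog,bpi_sdlog Lognormal parameters of intronic length.
#' @param dbp_meanlog,dbp_sdlog Lognormal magnitude of `|delta bpi|` added
#'   to the 100-base filter floor.
#' @param dgc_mean Mean of the exponential magnitude of `|delta GCi|`
#'   added to the 0.1-point filter floor.
#' @param sub_threshold_fraction Fraction of pairs constructed below both
#'   filter thresholds (removed by the negligible-delta filter).
#' @param repeat_insertion_rate,repeat_gc Target masked-bp fraction and GC
#'   percent of inserted repeats for [insert_repeats()].
#' @param mutation_rate Per-residue substitution rate turning species-m
#'   proteins into species-z proteins (RBH must rediscover the pairing).
#' @param protein_len_range,n_introns_range Ranges for protein length (aa)
#'   and internal introns per gene.
#' @param mr_meanlog,mr_sdlog Lognormal parameters of per-specimen
#'   mass-specific metabolic rate, per species (named vectors `m`, `z`).
#' @param trace_noise_frac Gaussian noise sd on simulated traces, as a
#'   fraction of the oxygen-content range.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_genes = 500L,
                         class_probs = c(`N/P` = 0.60, `N/N` = 0.20,
                                         `P/N` = 0.05, `P/P` = 0.15),
                         gci_mean = 40, gci_sd = 5, gci_shape = 4,
                         bpi_meanlog = 7.5, bpi_sdlog = 1,
                         dbp_meanlog = 5.5, dbp_sdlog = 1,
                         dgc_mean = 2,
                         sub_threshold_fraction = 0.05,
                         repeat_insertion_rate = 0.05, repeat_gc = 60,
                         mutation_rate = 0.02,
                         protein_len_range = c(80L, 300L),
                         n_introns_range = c(1L, 4L),
                         mr_meanlog = c(m = 4.5, z = 5.0),
                         mr_sdlog = c(m = 0.25, z = 0.25),
                         trace_noise_frac = 0.01) {
  stopifnot(length(class_probs) == 4L, all(class_probs >= 0),
            abs(sum(class_probs) - 1) < 1e-9,
            sub_threshold_fraction >= 0, sub_threshold_fraction < 1,
            repeat_insertion_rate >= 0, repeat_insertion_rate <= 0.5,
            mutation_rate >= 0, mutation_rate <= 1)
  names(class_probs) <- DELTA_CLASSES
  structure(as.list(environment()), class = "synth_config")
}

rskewnorm <- function(n, mean, sd, shape) {
  delta <- shape / sqrt(1 + shape^2)
  omega <- sd / sqrt(1 - 2 * delta^2 / pi)
  xi <- mean - omega * delta * sqrt(2 / pi)
  u0 <- rnorm(n); u1 <- rnorm(n)
  z <- delta * abs(u0) + sqrt(1 - delta^2) * u1
  xi + omega * z
}

# closed-form population skewness of the skew-normal, for oracle use
skewnorm_population_sk <- function(shape) {
  delta <- shape / sqrt(1 + shape^2)
  b <- delta * sqrt(2 / pi)
  (4 - pi) / 2 * b^3 / (1 - b^2)^1.5
}

# random sequence with an exact G+C count
random_seq_counts <- function(len, gc_count) {
  v <- sample(c("A", "T"), len, replace = TRUE)
  if (gc_count > 0L) {
    v[sample.int(len, gc_count)] <- sample(c("G", "C"), gc_count, replace = TRUE)
  }
  paste(v, collapse = "")
}

# nudge a GC count until 100*c/len differs from gref by at least min_mag
# in the direction `sgn` (or by less than min_mag when sgn == 0)
adjust_gc_count <- function(cnt, len, gref, sgn, min_mag = 0.1) {
  cnt <- max(0L, min(len, cnt))
  repeat {
    d <- gref - 100 * cnt / len
    if (sgn == 0) {
      if (abs(d) < min_mag) return(cnt)
      cnt <- cnt + if (d > 0) 1L else -1L
    } else {
      if (sign(d) == sgn && abs(d) >= min_mag) return(cnt)
      cnt <- cnt - sgn * 1L
    }
    if (cnt < 0L || cnt > len) {
      abort("Infeasible GC magnitude constraint for this intron length.",
            class = "introdelta_config_error")
    }
  }
}

#' Generate a synthetic two-species ortholog set
#'
#' Constructs `n_genes` orthologous gene pairs whose (delta bpi, delta GCi)
#' signs follow class labels drawn from `class_probs`, with magnitudes
#' guaranteed above the negligible-delta filter thresholds -- except an
#' exact `sub_threshold_fraction` of pairs constructed below both
#' thresholds. Intronic GC counts are exact, so the recorded truth deltas
#' equal what the pipeline measures. Proteins of species z are mutated
#' copies of species m's, so reciprocal-best-hit orthology can rediscover
#' the true pairing. Each species is assembled into a single-contig genome
#' with a GFF3-compatible gene/mRNA/exon/CDS structure that round-trips
#' through [load_species_dataset()].
#'
#' @param cfg A [synth_config()].
#' @param species_ids Length-2 character vector of species names.
#' @return List with `ds_m`, `ds_z` ([species_dataset()]s, each carrying
#'   `contigs` and `gff` fields for serialisation) and `truth` (list:
#'   `pairs` tibble with per-pair class and exact deltas, `species`
#'   tibble, `cfg`).
#' @export
generate_species_pair <- function(cfg, species_ids = c("species_m", "species_z")) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed, generate_species_pair_impl(cfg, species_ids))
}

generate_species_pair_impl <- function(cfg, species_ids) {
  n <- cfg$n_genes
  classes <- sample(DELTA_CLASSES, n, replace = TRUE, prob = cfg$class_probs)
  n_sub <- round(cfg$sub_threshold_fraction * n)
  sub <- rep(FALSE, n)
  if (n_sub > 0L) sub[sample.int(n, n_sub)] <- TRUE

  sign_bp <- ifelse(substr(classes, 1, 1) == "P", 1L, -1L)
  sign_gc <- ifelse(substr(classes, 3, 3) == "P", 1L, -1L)

  L_m <- pmax(200L, as.integer(round(rlnorm(n, cfg$bpi_meanlog, cfg$bpi_sdlog))))
  dbp <- 100L + as.integer(round(rlnorm(n, cfg$dbp_meanlog, cfg$dbp_sdlog)))
  dgc <- pmin(0.1 + rexp(n, 1 / cfg$dgc_mean), 25)
  gci_m <- pmin(95, pmax(5, rskewnorm(n, cfg$gci_mean, cfg$gci_sd, cfg$gci_shape)))

  # lengths: delta_bpi = L_m - L_z, sign per class; sub-threshold |delta| <= 99
  L_m[sub] <- pmax(L_m[sub], 2000L)
  L_z <- integer(n)
  L_z[sub] <- L_m[sub] - sample(c(-99:-1, 1:99), sum(sub), replace = TRUE)
  reg <- !sub
  L_m[reg] <- pmax(L_m[reg], ifelse(sign_bp[reg] > 0, dbp[reg] + 150L, 200L))
  L_z[reg] <- L_m[reg] - sign_bp[reg] * dbp[reg]

  c_m <- pmax(0L, pmin(L_m, as.integer(round(gci_m / 100 * L_m))))
  g_m <- 100 * c_m / L_m
  c_z <- integer(n)
  for (i in seq_len(n)) {
    target <- if (sub[i]) g_m[i] else g_m[i] - sign_gc[i] * dgc[i]
    c0 <- as.integer(round(target / 100 * L_z[i]))
    c_z[i] <- adjust_gc_count(c0, L_z[i], g_m[i],
                              if (sub[i]) 0L else sign_gc[i])
  }
  g_z <- 100 * c_z / L_z

  gene_m <- sprintf("m%05d", seq_len(n))
  gene_z <- sprintf("z%05d", seq_len(n))

  # proteins: species z as mutated copies of species m
  plen <- sample(seq(cfg$protein_len_range[1], cfg$protein_len_range[2]), n,
                 replace = TRUE)
  prot_m <- vapply(plen, function(L) {
    paste(c("M", sample(AA20, L - 1L, replace = TRUE)), collapse = "")
  }, character(1))
  prot_z <- vapply(prot_m, mutate_protein, character(1),
                   rate = cfg$mutation_rate, USE.NAMES = FALSE)

  k_introns <- sample(seq(cfg$n_introns_range[1], cfg$n_introns_range[2]), n,
                      replace = TRUE)

  build <- function(side) {
    ids <- if (side == "m") gene_m else gene_z
    prots <- if (side == "m") prot_m else prot_z
    Ls <- if (side == "m") L_m else L_z
    cs <- if (side == "m") c_m else c_z
    sp <- if (side == "m") species_ids[1] else species_ids[2]
    ord <- if (side == "m") seq_len(n) else sample.int(n)  # shuffle z genes
    assemble_species(sp, ids[ord], prots[ord], Ls[ord], cs[ord],
                     k_introns[ord])
  }
  ds_m <- build("m")
  ds_z <- build("z")

  truth <- list(
    pairs = tibble(
      gene_m = gene_m, gene_z = gene_z, class = classes,
      sub_threshold = sub,
      bpi_m = L_m, bpi_z = L_z, gci_m = g_m, gci_z = g_z,
      delta_bpi = L_m - L_z, delta_gci = g_m - g_z
    ),
    species = tibble(
      species_id = species_ids,
      mean_gci = c(mean(g_m), mean(g_z)),
      mean_bpi = c(mean(L_m), mean(L_z)),
      sk_target = rep(skewnorm_population_sk(cfg$gci_shape), 2)
    ),
    cfg = cfg
  )
  list(ds_m = ds_m, ds_z = ds_z, truth = truth)
}

mutate_protein <- function(p, rate) {
  if (rate == 0) return(p)
  v <- strsplit(p, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(AA20, v[i]), 1L)
  paste(v, collapse = "")
}

reverse_translate <- function(protein) {
  syn <- split(names(Biostrings::GENETIC_CODE), Biostrings::GENETIC_CODE)
  syn_n <- lengths(syn)
  syn_mat <- t(vapply(syn, function(x) rep_len(x, max(syn_n)), character(max(syn_n))))
  aa_all <- strsplit(protein, "", fixed = TRUE)
  lens <- lengths(aa_all)
  aa_vec <- unlist(aa_all)
  row <- match(aa_vec, rownames(syn_mat))
  pick <- 1L + floor(runif(length(aa_vec)) * syn_n[row])
  codons <- syn_mat[cbind(row, pick)]
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  vapply(seq_along(protein), function(i) {
    paste(c(codons[starts[i]:ends[i]], "TAA"), collapse = "")
  }, character(1))
}

# One species: genes laid head-to-tail on a single contig with random
# spacers; every exon carries CDS, so all introns are internal.
assemble_species <- function(species_id, ids, prots, Ls, cs, k_introns) {
  n <- length(ids)
  cds <- reverse_translate(prots)
  strands <- sample(c("+", "-"), n, replace = TRUE)

  segs <- character(n)
  gff_rows <- vector("list", n)
  intron_rows <- vector("list", n)
  offset <- 0L
  for (i in seq_len(n)) {
    intron_full <- random_seq_counts(Ls[i], cs[i])
    k <- k_introns[i]
    icuts <- if (k > 1L) sort(sample.int(Ls[i] - 1L, k - 1L)) else integer()
    ibounds <- cbind(c(1L, icuts + 1L), c(icuts, Ls[i]))
    intron_parts <- substring(intron_full, ibounds[, 1], ibounds[, 2])

    Lc <- nchar(cds[i])
    ccuts <- sort(sample.int(Lc - 1L, k))
    cbounds <- cbind(c(1L, ccuts + 1L), c(ccuts, Lc))
    cds_parts <- substring(cds[i], cbounds[, 1], cbounds[, 2])

    sense <- paste(as.vector(rbind(cds_parts, c(intron_parts, ""))),
                   collapse = "")
    glen <- nchar(sense)
    # sense-coordinate exon intervals
    ex_start <- integer(k + 1L); ex_end <- integer(k + 1L)
    pos <- 1L
    for (e in seq_len(k + 1L)) {
      w <- nchar(cds_parts[e])
      ex_start[e] <- pos; ex_end[e] <- pos + w - 1L
      pos <- pos + w + if (e <= k) nchar(intron_parts[e]) else 0L
    }
    if (strands[i] == "-") {
      genomic <- revcomp(sense)
      st <- glen - ex_end + 1L; en <- glen - ex_start + 1L
      ex_start <- rev(st); ex_end <- rev(en)
    } else {
      genomic <- sense
    }
    spacer <- random_seq_counts(100L, 40L)
    g0 <- offset + nchar(spacer)
    segs[i] <- paste0(spacer, genomic)
    offset <- offset + nchar(segs[i])

    gff_rows[[i]] <- tibble(
      type = c("gene", "mRNA", rep(c("exon", "CDS"), each = k + 1L)),
      start = g0 + c(1L, 1L, ex_start, ex_start),
      end = g0 + c(glen, glen, ex_end, ex_end),
      strand = strands[i],
      ID = c(ids[i], paste0(ids[i], ".t1"), rep(NA_character_, 2L * (k + 1L))),
      Parent = c(NA_character_, ids[i], rep(paste0(ids[i], ".t1"), 2L * (k + 1L)))
    )
    intron_rows[[i]] <- tibble(
      gene_id = ids[i], species_id = species_id, sequence = intron_full,
      bpi = Ls[i], gci = 100 * cs[i] / Ls[i], n_introns = k
    )
  }
  contig <- paste(segs, collapse = "")
  genes <- tibble(
    gene_id = ids, tx_id = paste0(ids, ".t1"), strand = strands,
    n_exons = k_introns + 1L, has_ambiguity = FALSE,
    malformed_cds = FALSE, internal_stop = FALSE, n_introns = k_introns
  )
  ds <- species_dataset(
    species_id = species_id, genes = genes,
    cds_seqs = setNames(cds, ids), protein_seqs = setNames(prots, ids),
    introns = list_rbind(intron_rows),
    gcg = gc_content(contig)
  )
  ds$contigs <- setNames(contig, "chr1")
  ds$gff <- list_rbind(gff_rows) |> mutate(seqid = "chr1", .before = 1)
  ds
}

#' Splice repeat elements into a dataset's introns
#'
#' Inserts library consensus copies (random strand) at random positions of
#' each intronic sequence until the inserted fraction of the grown
#' sequence approximates `rate`. The final copy may be a random consensus
#' window (never shorter than `min_piece`, so a substring-seeded masker
#' still finds it), with the sub-window remainder resolved by stochastic
#' rounding, keeping the realised insertion fraction unbiased even for
#' short introns. Only the intronic-sequence table is mutated (lengths
#' and GC re-measured); the genomic FASTA of the dataset is left
#' untouched. Insertion totals are recorded for recovery scoring.
#'
#' @param ds A [species_dataset()].
#' @param lib A [repeat_library()].
#' @param rate Target inserted-bp fraction in `[0, 0.5]`.
#' @param seed Integer seed.
#' @param min_piece Smallest insertable consensus window, bases.
#' @return List `ds` (modified dataset) and `truth` (tibble: `gene_id`,
#'   `inserted_bp`, `original_bp`).
#' @export
insert_repeats <- function(ds, lib, rate, seed = 1L, min_piece = 15L) {
  stopifnot(inherits(ds, "species_dataset"), inherits(lib, "repeat_library"),
            rate >= 0, rate <= 0.5)
  if (rate == 0) {
    return(list(ds = ds,
                truth = tibble(gene_id = ds$introns$gene_id,
                               inserted_bp = 0L,
                               original_bp = ds$introns$bpi)))
  }
  withr::with_seed(seed, {
    els <- lib$elements
    intr <- ds$introns
    truth <- vector("list", nrow(intr))
    splice <- function(s, piece) {
      pos <- sample.int(nchar(s) + 1L, 1L) - 1L
      paste0(substr(s, 1L, pos), piece, substr(s, pos + 1L, nchar(s)))
    }
    for (i in seq_len(nrow(intr))) {
      s <- intr$sequence[i]
      orig <- nchar(s)
      target <- orig * rate / (1 - rate)
      inserted <- 0L
      repeat {
        remaining <- target - inserted
        if (remaining < min_piece) {
          # stochastic rounding of the sub-window remainder: unbiased
          if (remaining > 0 && runif(1) < remaining / min_piece) {
            el <- els[sample.int(length(els), 1L)]
            st <- sample.int(nchar(el) - min_piece + 1L, 1L)
            piece <- substr(el, st, st + min_piece - 1L)
            if (runif(1) < 0.5) piece <- revcomp(piece)
            s <- splice(s, piece)
            inserted <- inserted + min_piece
          }
          break
        }
        el <- els[sample.int(length(els), 1L)]
        plen <- min(nchar(el), as.integer(floor(remaining)))
        st <- sample.int(nchar(el) - plen + 1L, 1L)
        piece <- substr(el, st, st + plen - 1L)
        if (runif(1) < 0.5) piece <- revcomp(piece)
        s <- splice(s, piece)
        inserted <- inserted + plen
      }
      intr$sequence[i] <- s
      truth[[i]] <- tibble(gene_id = intr$gene_id[i],
                           inserted_bp = inserted, original_bp = orig)
    }
    intr$bpi <- nchar(intr$sequence)
    intr$gci <- gc_or_na(intr$sequence)
    ds$introns <- intr
    list(ds = ds, truth = list_rbind(truth))
  })
}

#' Generate a synthetic oxygen-depletion trace
#'
#' Linear depletion of total chamber oxygen at `true_rate_ug_h`, observed
#' at `n_points` equally spaced times with Gaussian noise of standard
#' deviation `noise_frac` times the depleted range. Duration is chosen so
#' the oxygen content falls by `fall_target` over the trace.
#'
#' @param true_rate_ug_h True consumption rate, ug O2 h^-1.
#' @param n_points Number of readings.
#' @param noise_frac Noise sd as a fraction of the oxygen-content range.
#' @param fall_target Relative fall of oxygen content over the trace.
#' @param volume_l,temp_c,mass_kg,ap_kpa,svp_kpa,alpha,salinity,species_id
#'   Chamber metadata; see [respirometry_trace()].
#' @param seed Integer seed.
#' @return A `respirometry_trace` with attribute `true_rate_ug_h`.
#' @export
generate_trace <- function(true_rate_ug_h, n_points = 200,
                           noise_frac = 0.01, fall_target = 0.15,
                           volume_l = 0.1, temp_c = 26, mass_kg = 0.005,
                           ap_kpa = 101.325, svp_kpa = 2.34, alpha = 0.4,
                           salinity = 0, species_id = NA_character_,
                           seed = 1L) {
  stopifnot(true_rate_ug_h > 0, n_points >= 10)
  sat <- oxygen_concentration(partial_pressure_o2(ap_kpa, svp_kpa), alpha)
  o2_0 <- sat * volume_l * 1000
  duration <- fall_target * o2_0 / true_rate_ug_h
  time_h <- seq(0, duration, length.out = n_points)
  withr::with_seed(seed, {
    o2 <- o2_0 - true_rate_ug_h * time_h
    if (noise_frac > 0) {
      o2 <- o2 + rnorm(n_points, sd = noise_frac * (fall_target * o2_0))
    }
    tr <- respirometry_trace(
      time_h = time_h, reading = o2 / (volume_l * 1000) / sat * 100,
      volume_l = volume_l, temp_c = temp_c, mass_kg = mass_kg,
      ap_kpa = ap_kpa, svp_kpa = svp_kpa, alpha = alpha,
      salinity = salinity, species_id = species_id)
    attr(tr, "true_rate_ug_h") <- true_rate_ug_h
    tr
  })
}

#' Write a synthetic run to disk
#'
#' Emits, under one directory named by seed, per-species genome FASTA,
#' GFF3 annotation and intron TSV, plus the truth tables as JSON -- the
#' full input surface of the pipeline.
#'
#' @param sim Output of [generate_species_pair()].
#' @param dir Parent directory.
#' @return The run directory, invisibly.
#' @export
write_synthetic_run <- function(sim, dir) {
  run_dir <- file.path(dir, sprintf("run_seed%d", sim$truth$cfg$seed))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  for (ds in list(sim$ds_m, sim$ds_z)) {
    base <- file.path(run_dir, ds$species_id)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(ds$contigs),
                                paste0(base, ".fa"))
    write_gff3(ds$gff, paste0(base, ".gff3"))
    write_intron_table(ds, paste0(base, ".introns.tsv"))
  }
  truth <- sim$truth
  truth$cfg <- unclass(truth$cfg)
  jsonlite::write_json(truth, file.path(run_dir, "truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(run_dir)
}

write_gff3 <- function(gff, path) {
  attrs <- paste0(
    ifelse(is.na(gff$ID), "", paste0("ID=", gff$ID)),
    ifelse(is.na(gff$ID) | is.na(gff$Parent), "", ";"),
    ifelse(is.na(gff$Parent), "", paste0("Parent=", gff$Parent))
  )
  lines <- paste(gff$seqid, "introdelta", gff$type, gff$start, gff$end,
                 ".", gff$strand, ".", attrs, sep = "\t")
  readr::write_lines(c("##gff-version 3", lines), path)
  invisible(path)
}
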