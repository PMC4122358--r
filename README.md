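# introdelta

Comparative analysis of intron architecture between genomes, for
molecular evolutionists asking whether intron **length** (bpi, the summed
length of a gene's internal introns) and intron **GC content** (GCi)
change together — and whether those changes track the organisms'
temperature-corrected metabolic rate, as the metabolic-rate hypothesis of
genome evolution predicts.

The package implements the full desk pipeline around that question:

- **Gene models and QC** — load genome FASTA + GFF3, pick one transcript
  per protein-coding gene (longest CDS), extract spliced CDS and the
  concatenation of *internal* introns (introns in the 5'/3' UTR flanks
  are discarded), and flag sequences with base ambiguity, malformed
  reading frames or internal stop codons.
- **Orthology** — one-to-one orthologs by reciprocal best hits (RBH) on
  protein sequences: a pair *(a, b)* is kept iff *b* is *a*'s unique
  top-scoring hit and vice versa. The built-in scorer is Smith–Waterman
  local alignment (BLOSUM62, affine gaps 11/1); 12-column tabular hit
  files from an external aligner can be imported instead, with an e-value
  threshold (default 1e-10). CDS orthology is then extended to the two
  genes' intronic sequences.
- **Repeat masking** — a substring-seeded library masker (plus
  low-complexity run masking) or an imported external mask; per-cohort
  statistics of masked length percent and masked-base GC, so every delta
  analysis runs *before* and *after* masking.
- **Deltas and sign classes** — per ortholog pair, Δbpi = bpi_m − bpi_z
  and ΔGCi = GCi_m − GCi_z. Pairs with |ΔGCi| < 0.1 points and/or
  |Δbpi| < 100 bases are disregarded (strict inequality; the removed
  fraction is reported). The rest are classified by sign into
  **N/P** (shorter and GC-richer in the first species), **N/N**, **P/N**,
  **P/P**; the dominant class is tested against the uniform null
  p₀ = 1/4 with an exact one-sided binomial tail
  P(X ≥ k) = Σ_{j≥k} C(n,j) p₀^j (1−p₀)^{n−j}, with
  Benjamini–Hochberg adjustment across comparisons.
- **Respirometry and metabolic rate** — closed-chamber oxygen traces:
  pO₂ = (AP − SVP)·0.2096, [O₂] = pO₂·α, total chamber oxygen vs. time
  fitted by least squares (traces falling > 20% are rejected), the
  mass-specific rate MR₀ (mgO₂·kg⁻¹·h⁻¹) temperature-corrected with the
  Boltzmann factor **MR = MR₀·e^{E/kT}** (E = 0.65 eV,
  k = 8.62×10⁻⁵ eV·K⁻¹).
- **Statistics** — distribution skewness (g₁), tie-aware Spearman rank
  correlation, and the Student–Newman–Keuls stepwise range test for
  among-species MR differences.
- **Synthetic data** — a seeded generator producing two-species ortholog
  sets with controlled class structure, skewed GCi distributions, repeat
  insertions of known GC, and noisy linear oxygen-depletion traces, with
  the generating truth recorded — the package's recovery tests and
  acceptance script run on it.

Everything is tibble-first: results chain with the pipe, fitted objects
have `tidy()`/`glance()` methods, and `autoplot()`/`plot_*()` give
ggplot2 figures.

## Worked example

```r
library(introdelta)

cfg <- synth_config(seed = 42, n_genes = 200)
sim <- generate_species_pair(cfg, species_ids = c("medaka_like", "zebrafish_like"))

kept <- sim$truth$pairs[, c("gene_m", "gene_z")] |>
  extend_to_introns(sim$ds_m, sim$ds_z) |>
  compute_deltas(species = c("medaka_like", "zebrafish_like")) |>
  filter_deltas()

removed_fraction(kept)
#> [1] 5

cf <- class_frequencies(classify_deltas(kept),
                        comparison = "medaka_like|zebrafish_like")
tidy(cf)
#>   class     n   pct
#> 1 N/P     100 52.6
#> 2 N/N      50 26.3
#> 3 P/N       8  4.21
#> 4 P/P      32 16.8
binomial_test_top_class(cf)
#>   top_class     k     n null_p  p_value
#> 1 N/P         100   190   0.25 3.51e-16
```

5% of the 200 generated pairs were below the negligible-delta thresholds
and removed; among the 190 informative pairs the N/P class (intron
shorter and GC-richer in the first species) dominates at 52.6%, and the
exact binomial test rejects the uniform four-class null at p ≈ 3.5e-16 —
the concomitant shortening-plus-GC-enrichment signal the comparison is
designed to detect.

A respirometry trace works the same way:

```r
tr <- generate_trace(50, noise_frac = 0.01, seed = 4, temp_c = 26)
(f <- consumption_rate(tr))
#> <o2_fit> 50.2 ugO2/h (MR0 10 mgO2/kg/h), R^2 0.9986, fall 13.6%
boltzmann_correct(f$mr0, temp_c = 26)
#> [1] 8.885e+11
```

The fitted depletion slope (50.2 µgO₂/h against a true 50) gives a
mass-specific rate of 10 mgO₂·kg⁻¹·h⁻¹, which the Boltzmann factor at
26 °C scales for cross-temperature comparison.

`run_pipeline()` composes all stages over any number of species —
C(S, 2) pairwise comparisons, both masking variants, species summaries,
class frequencies with adjusted binomial p-values, the Spearman matrix
over mean Δbpi/ΔGCi/ΔMR and the SNK matrix on MR.

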