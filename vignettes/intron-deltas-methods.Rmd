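---
title: "Methods: orthology-anchored intron deltas and metabolic-rate correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orthology-anchored intron deltas and metabolic-rate correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introdelta)
```

## The question and the comparison design

Within one genome, intron length (bpi) and intronic GC content (GCi)
often show no simple linear relationship: a species-level snapshot mixes
genes under very different constraints. The design implemented here
compares *the same gene* across two genomes instead. For each one-to-one
ortholog pair the signed differences

\[
\Delta bpi = bpi_m - bpi_z,\qquad \Delta GCi = GCi_m - GCi_z
\]

are computed (first species minus second), and each informative pair is
assigned to one of four sign classes: N/P (shorter and GC-richer in the
first species), N/N, P/N, P/P. If intron shortening and GC enrichment
are coupled — as the metabolic-rate hypothesis predicts when the first
species has the higher temperature-corrected metabolic rate — the N/P
class should dominate, and the rare opposite class P/N should be
depleted. Because deltas are computed per orthologous gene, dataset-size
differences between genomes cancel, which is the point of anchoring the
analysis on orthology.

The approach assumes (i) reciprocal-best-hit pairs are true one-to-one
orthologs, (ii) the concatenated internal introns of the selected
transcript represent the gene's intronic state, and (iii) pairwise
deltas can be summarised independently per comparison. The last
assumption is the weakest: deltas among S species are not
phylogenetically independent (each species enters S−1 comparisons), so
the cross-comparison correlations must be read as descriptive, not as
independent-sample inference.

## Gene models and what counts as an internal intron

One transcript represents each gene: the one with the longest summed
CDS, ties broken by lexicographically smallest transcript id — a
deterministic stand-in for unavailable canonical-transcript annotations.
Introns are gaps between consecutive exons. An intron is *internal* when
it lies strictly between the first and last CDS-bearing exons of that
transcript; introns entirely within the 5′ or 3′ UTR are the flanking
introns the analysis discards. The CDS span is the natural anchor
because orthology is established on coding sequence; still, the
alternative reading — drop the first and last intron of the transcript
regardless of CDS — is available via
`extract_internal_introns(internal_rule = "trim_terminal")`, since
annotation conventions differ on where UTR exons are recorded.

Base-composition conventions: GC percent is
$100\,(G+C)/(A+C+G+T)$, case-insensitive, with hard-masked `N` excluded
from numerator and denominator (so GCi after masking is the GC of the
surviving bases); raw-input QC discards sequences containing any
ambiguity code. CDS whose length is not a codon multiple, or with a stop
codon before the terminal one, are dropped from orthology input.
Coordinates are 1-based closed internally (the IRanges convention);
interval-file I/O for masks uses the conventional 0-based half-open
encoding.

## Orthology

Reciprocal best hits on proteins: pair (a, b) is retained iff b is a's
unique top-scoring hit A→B and a is b's unique top-scoring hit B→A.
Ties for the top score drop the gene — preserving the one-to-one
guarantee is worth losing an occasional ambiguous pair. The built-in
scorer is Smith–Waterman local alignment with BLOSUM62 and affine gaps
(open 11, extend 1), the parameterisation protein BLAST defaults to. It
reports raw scores, not e-values: e-value calibration (Karlin–Altschul
statistics over database sizes) is out of scope, so the built-in path
uses a raw-score floor (`score_min`, default 50 — roughly the score of
a short confident local match, well above the 20–40 range that unrelated
proteins of this length reach by chance), while imported 12-column
tabular hits keep their aligner's e-values and are filtered at the
conventional 1e-10.

## Repeat masking

The built-in masker hard-masks every exact occurrence, on either strand,
of a library-consensus substring of length ≥ `min_match` (default 15, a
length at which chance matches in a ~10 Mb intron cohort are expected
well below one), implemented by seeding with consensus k-mers and
merging the hit intervals, plus single-base runs ≥ 20 as
low-complexity. This is deliberately an exact-substring matcher, not a
Smith–Waterman repeat finder: no fidelity to heuristic repeat-annotation
tools is claimed, and `import_external_mask()` is the high-fidelity path
for masks produced by such tools. Masking is idempotent, and the GC
budget decomposes exactly:
\( bpi \cdot GCi_{before} = masked\_bp \cdot GC_{masked} + (bpi - masked\_bp)\cdot GCi_{after} \),
which the tests assert to numerical precision. "After masking" analyses
re-measure sequences with masked bases removed from both length and GC;
the variant that drops whole masked sequences can be had by filtering on
`masked_bp` before `apply_mask()`.

## The negligible-delta filter and the binomial test

Pairs with $|\Delta GCi| < 0.1$ points **and/or** $|\Delta bpi| < 100$
bases are disregarded. The "and/or" is read as OR — a pair must be
informative on *both* axes to enter the joint sign classification —
with `rule = "and"` available as the laxer reading. The inequality is
strict, so boundary values (exactly 0.1 point or 100 bp) are retained.
The removed fraction per comparison is reported alongside the results.

The dominant class is tested with the exact one-sided upper tail
$P(X \ge k_{top})$, $X \sim \mathrm{Binomial}(n, p_0)$, summed from the
probability mass function directly — no normal approximation at any n
used here. The null $p_0 = 1/4$ (four classes equiprobable) is the
package's choice of null; a sharper alternative — top class against the
runner-up on their union with $p_0 = 1/2$ — is available via
`null = "top2"`. Benjamini–Hochberg adjustment is applied across the
family of all comparisons × masking variants, since that is the set of
tests actually reported together.

## Respirometry and the Boltzmann correction

From a closed, stirred chamber: $pO_2 = (AP - SVP)\cdot 0.2096$ (kPa;
0.2096 is the O₂ fraction of air), $[O_2] = pO_2 \cdot \alpha$ in
mg·L⁻¹, and total chamber oxygen $[O_2]\cdot V$ (µg after ×1000). The
consumption rate is the negated least-squares slope of total oxygen
vs. time. Quality control mirrors good chamber practice: the first 10%
of the trace is trimmed by default (electrode settling and animal
adaptation), the oxygen fall over the analysed window must not exceed
20% (hypoxia changes behaviour), and a non-negative slope invalidates
the trace. $\alpha$ and SVP are temperature- and salinity-specific and
must be supplied by the user; the package ships no solubility table as
normative data.

Mass-specific rate (mgO₂·kg⁻¹·h⁻¹) is temperature-corrected as
$MR = MR_0\, e^{E/kT}$ with $E = 0.65$ eV (the canonical activation
energy of metabolic processes in the metabolic theory of ecology;
configurable) and $k = 8.62\times10^{-5}$ eV·K⁻¹. The sign convention
multiplies by $e^{E/kT}$, which is strictly decreasing in temperature —
warmer measurements receive smaller factors — and preserves rate ratios
at equal temperature. The correction factor is enormous in absolute
terms (~1.5e11 at 20 °C); only differences and ratios across
temperatures are meaningful. Log-normalised reporting supports both
natural log (default) and base 10, since box-plot conventions differ.

## Statistics

Skewness is the moment coefficient $g_1 = m_3/m_2^{3/2}$ (the adjusted
$G_1$ variant is a switch); it summarises the asymmetry of a species'
GCi distribution. Spearman's rho is the Pearson correlation of
mid-ranks, tie-aware by construction; on untied data it equals the
classical $1 - 6\sum d^2/(n(n^2-1))$ identity exactly. The default
p-value is the two-sided t approximation with $n-2$ df, appropriate for
the ~10 comparison-level points these analyses produce; a permutation
option (exhaustive for n ≤ 7, 20 000 seeded permutations otherwise) is
provided for small samples where the approximation is doubtful.

The Student–Newman–Keuls test ranks group means after a one-way ANOVA
and works down the studentized ranges: a span of r means is significant
when its range statistic exceeds $q_{1-\alpha}(r, df_e)$, and any
comparison enclosed in a non-significant span is declared
non-significant without testing (the containment rule). Critical values
come from the studentized-range distribution function (`qtukey`)
numerically, not from transcribed tables. Unequal group sizes use the
pairwise standard error $\sqrt{MSE/2\,(1/n_i + 1/n_j)}$. Under a
complete null the procedure's family-wise error equals the per-step
alpha; the test suite checks it stays below 0.08 at alpha 0.05 over
1000 simulations.

## What the synthetic generator emulates — and what it does not

`generate_species_pair()` draws, per ortholog pair, a sign class from
`class_probs`, magnitudes $|\Delta bpi| \sim 100 + \mathrm{Lognormal}(5.5, 1)$
and $|\Delta GCi| \sim 0.1 + \mathrm{Exp}(\text{mean } 2)$ — both
guaranteed above the filter thresholds — and an exact
`sub_threshold_fraction` of pairs constructed below *both* thresholds.
Intronic GC for the first species is skew-normal (mean 40, sd 5, shape
4, truncated to (0,100)); lengths are lognormal (meanlog 7.5, sdlog 1).
These defaults are the study conditions the recovery tests run under:
teleost-like mean GCi around 40% with positive skew near 0.8,
heavy-tailed intron lengths with means in the thousands of bases, a
dominant N/P class (0.60) with P/N rarest (0.05), and a sub-threshold
fraction (0.05) comfortably under the ten-percent mark typical of
informative comparisons between non-sister species. GC counts are
realised exactly (count-constructed sequences, then a ±1 adjustment so
the measured delta respects the drawn sign and the 0.1-point floor), so
the recorded truth equals what the pipeline measures to the last bit —
that is what makes exact recovery assertions possible. Proteins of the
second species are point-mutated copies (rate 0.02) so RBH can
rediscover the pairing; genes are laid onto a single contig per species
with random strands and fully CDS-covered exons, and the emitted
FASTA/GFF3 round-trips through the loader.

What it does **not** emulate: real molecular evolution (no substitution
model beyond uniform point mutation, no indels in proteins, no codon
bias), UTR-flanking introns, isoform structure, inter-gene dependence,
isochore spatial structure along chromosomes, or genuine repeat-family
phylogenies (insertions are clean consensus windows). Passing recovery
tests therefore demonstrates that the pipeline measures what it claims
on data with known structure — not that real genomes satisfy the
generator's assumptions.

`insert_repeats()` splices consensus windows until the inserted
fraction of the grown sequence hits the target rate, resolving the last
sub-window remainder by stochastic rounding so the realised fraction is
unbiased even for short introns; windows never drop below 15 bases so a
substring-seeded masker can still find them. `generate_trace()` produces
linear depletion with Gaussian noise (sd = 1% of the depleted range by
default) and a 15% fall target, inside the 20% QC bound.

## Numerical choices and degenerate inputs

- Exact binomial tails sum `dbinom` mass directly; the suite
  cross-checks a multiplicative pmf recurrence and the regularized
  incomplete beta identity to 1e-12.
- `gc_content` errors on all-N input rather than returning NaN;
  bookkeeping tables carry `NA` for empty intronic sequences instead.
- Zero-delta records cannot reach classification (the filter removes
  them); `classify_deltas` treats one as a contract violation.
- SNK refuses zero-residual-variance configurations; Spearman refuses
  constant vectors; skewness refuses zero variance. Silent zeros would
  be wrong answers in each case.
- Tie handling is explicit everywhere ties have a meaning: RBH drops
  tied-best genes; Spearman uses mid-ranks; the transcript choice
  tie-breaks lexicographically.

## Problem sizes

The shipped tests and the acceptance script run, per invocation: one
2000-pair two-species recovery study, a 300-sequence masking cohort at
5% insertion, 50 toy proteomes (≤ 8 sequences each) plus three 15-gene
mutated-copy proteomes for RBH oracles, a dense exact-binomial grid
(n ≤ 200), 1000 SNK null simulations and 300 seeded trace replicates.
These sizes give the Monte-Carlo assertions comfortable margins (3
binomial SD on class frequencies; 0.5% on mean slope bias) on a single
CPU in a few minutes.

## Known limitations

- Built-in alignment scores are raw; cross-aligner comparability
  requires the tabular importer.
- The masker's exact-substring semantics underestimate diverged repeat
  copies by design; import external masks for real annotations.
- Pairwise deltas among S species are correlated by shared species;
  no phylogenetic correction is attempted.
- The Spearman t-approximation is rough at n = 10; the permutation
  option exists precisely for that range, and second-decimal differences
  between p-value methods should be expected.
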