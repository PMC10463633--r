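---
title: "Isochore segmentation and the GC architecture of tandem gene arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isochore segmentation and the GC architecture of tandem gene arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isobloom)
```

## The scientific question

Mammalian genomes are mosaics of isochores: long segments (100 kb to
several Mb) with locally homogeneous GC content. AT-rich isochores are
enriched for tandemly arrayed gene families with "outward-looking"
functions — olfactory receptors, keratin-associated proteins, epidermal
barrier and xenobiotic genes — while GC-rich isochores hold broadly
expressed singleton genes with CpG-island promoters. Two population-genetic
forces plausibly maintain this architecture: CpG-biased mutation (methylated
CpG deaminates to TpG, eroding GC where recombination is scarce) and
GC-biased gene conversion (gBGC), which raises GC where crossovers
concentrate. `isobloom` implements the analysis pipeline that quantifies
this architecture, plus a synthetic-data generator so that every stage runs
— and is tested — against inputs with known truth.

The pipeline stages are:

1. **Isochore segmentation** of a genome sequence, with GC ranking and
   decile binning.
2. **Per-gene sequence features**: feature-wise GC, metagene GC
   trajectories, promoter CpG observed/expected.
3. **Classification and diversity**: iterative 3×3 k-means on trajectories;
   gene-name prefix derivation; Shannon prefix diversity and
   tandem-neighbour counts per isochore.
4. **Population overlays**: de novo mutation density, sex-specific
   crossover rates, PRDM9 peak enrichment, rare-variant ratios, expression
   breadth, A/B compartment consensus.
5. **Cross-species tandem arrays**: bookend-ortholog clipping and
   feature-level GC decomposition.
6. **Phylogenetic regression** (`pgls()`): cluster GC on log paralog count
   with Pagel's λ estimated by maximum likelihood.

## Isochore segmentation

`segment_sequence()` performs recursive binary segmentation. For a segment,
every split point *i* is scored by the weighted squared GC-fraction
difference

$$\delta(i) = \frac{n_L\,n_R}{N}\,(p_L - p_R)^2,$$

where $n_L, n_R$ are called (non-N) base counts on each side,
$N = n_L + n_R$, and $p_L, p_R$ the GC fractions. The argmax split is
accepted iff the scaled halting statistic

$$s(i^*) = \frac{4\,\delta(i^*)}{\bar p\,(1 - \bar p)}$$

exceeds `t0` (default **275**) and both children are at least
`min_segment_bp` (default **3000 bp**) long; accepted children are split
recursively. $s$ is approximately four times the binomial
log-likelihood-ratio statistic for a single changepoint, which makes the
halting rule scale-free: homogeneous sequence stays whole at any length,
while a genuine GC shift grows $s$ linearly with segment length. The
default threshold corresponds to isochore-scale resolution (a few thousand
isochores on a human-sized genome). An alternative reading of the halting
rule in which the statistic itself scales with segment length was rejected
during design because it splits arbitrarily long homogeneous sequence — it
would make the null behaviour (one segment for one composition) impossible.

Numerical choices: N bases are excluded from numerator and denominator of
every GC fraction; runs of ≥ 1000 N (`hard_gap_bp`) are assembly gaps that
no segment may cross; after segmentation, mostly-N segments are removed and
gaps shorter than `gap_filter_fraction` (default 1%) of the input are
dropped from the gap report. Ties in the argmax go to the lowest
coordinate. Isochores are ranked 1 = highest GC; deciles are equal-count
bins (sizes differing by at most one, the remainder going to the lowest
bins) with decile 1 the most AT-rich, ties broken by (chrom, start). Genes
are matched to isochores by transcription start site; a TSS in a removed
gap leaves the gene unassigned.

```{r segmentation-example, eval = FALSE}
g <- make_genome(data.frame(length_bp = c(50000, 50000),
                            target_gc = c(0.30, 0.60)), seed = 1)
segment_sequence(g)          # two isochores, breakpoint within ~20 bp
```

## Gene-level GC features

The promoter window is −750/+250 bp around the TSS in transcript
orientation: `[tss − 750, tss + 250)` on the plus strand and the mirrored
`[tss − 250, tss + 750)` on the minus strand (half-open coordinates).
Flanks (1 kb and 25 kb) exclude the gene body; introns are the body minus
exons; CDS GC uses exons intersected with the CDS span. Because G+C content
is invariant under reverse complement, all quantities are computed by
coordinate arithmetic only.

Metagene trajectories use non-overlapping 50-bp windows over 1-kb flanks
(20 windows per flank) and 100 equal-width bins over the gene body — body
bins scale with gene length, which is what makes rows comparable across
genes. The window step equals the window width; overlapping windows would
only smooth the rows without changing bin placement. Genes shorter than the
bin count get overlapping ceil/floor bins so every bin covers ≥ 1 bp.
Vectors are oriented 5′→3′; N-only windows are `NA` and are imputed by
row-wise linear interpolation before clustering.

Promoter CpG scoring follows the Gardiner-Garden observed/expected form:
observed = CG dinucleotide count in the window, expected = $n_C n_G / L$
over the same window ($L$ = called bases). When the expectation is zero the
ratio is reported as missing, never as zero.

## Classification and diversity

`iterative_kmeans()` runs k = 3 over all trajectories, then k = 3 within
each top cluster. The implementation is deliberately deterministic: rows
are ordered by (row mean, then columns), initial centers are taken at
quantile-spread positions of that ordering (10 spreads, best
within-cluster SS kept), and Lloyd iterations with fixed centers do not
depend on row order. This is stronger than seeded reproducibility — the
partition is invariant under permutation of the input rows, which the suite
verifies. Labels are renamed so mean promoter-region GC (upstream windows
covering −750..0 plus the first 5% of body bins) decreases with the index;
cluster 3.3 is therefore the most AT-biased.

Prefix derivation reduces a gene symbol to its family prefix: apply the
renaming table; replace digits (and other non-letter characters such as
hyphens, so KRTAP4-5 → KRTAP) with "\_"; truncate at the first "\_"
(CSN2A → CSN); single-letter leftovers consult an override table;
family-merge overrides (KCNT, KCNQ → KCN) apply last. The three tables
ship as editable TSVs under `inst/extdata` and can be replaced per run; no
online nomenclature service is consulted. Diversity per isochore is
Shannon's H in bits, $H = \sum_i p_i \log_2(1/p_i)$ over prefix
proportions, restricted to isochores with ≥ `min_genes` (default 10)
genes. A gene's tandem neighbours are same-prefix genes in its home
isochore, binned 0 / 1–4 / ≥5. The "multigene score" of an isochore — the
fraction of its genes with at least one same-prefix neighbour — is a
package convention exposed as `multigene_score()`, since no standard
definition exists for that summary.

## Population-genetic overlays

- **DNM density**: DNMs (deduplicated by position) pooled over the merged
  TSS–TES spans of an isochore's home genes, divided by the summed genic
  length, per kb; the isochore-wide analogue uses the whole span.
- **Crossovers** are assigned to the region containing the midpoint of
  their refined interval (the median of its two endpoints). Relative rate =
  per-bp count over the per-bp genomic mean for that sex, so the
  length-weighted mean over any complete tiling is exactly 1. A z-score
  standardization is available by flag; gene-level rates use gene ± 25 kb
  windows. Whether midpoints falling outside all regions still count in
  the genomic denominator is a flag (`include_unassigned`, default TRUE).
- **PRDM9**: only the top 10% of peaks by enrichment are kept (all peaks
  tied at the cutoff included — the retained count is `ceiling(0.1 n)` plus
  ties); a retained peak adds its full enrichment to the isochore whose
  genic span contains the peak midpoint. Both the raw sum and the
  per-genic-kb rate are reported, since the appropriate denominator depends
  on the downstream plot.
- **Variant ratios**: per gene (missense + LoF)/synonymous, missing when
  synonymous = 0; pooled per group as ratio of sums, so zero-synonymous
  genes still contribute their non-synonymous counts.
- **Expression breadth**: tissues with expression ≥ 5 (inclusive). The
  threshold is unit-agnostic configuration — published uses of this
  binarization disagree between TPM and RPKM at the same nominal value of
  5, so the package does not hard-code a unit.
- **Compartment consensus**: per tissue, a gene takes the A/B label of the
  compartment whose midpoint is nearest its TSS (isochores:
  midpoint-to-midpoint); A-counts over 21 tissues are binned 21 / 14–20 /
  7–13 / 1–6 / 0 (always A … always B), scaled proportionally via
  `round(cut · T/21)` for other tissue counts, with the always-A/always-B
  bins kept exact.

## Cross-species tandem arrays

`locate_cluster()` takes two bookend orthologs; if they share a scaffold,
the array region is the span strictly *between* them (the bookends
excluded; an inclusive mode exists for sensitivity analyses), and genes are
counted only when fully contained — containment rather than overlap avoids
crediting boundary genes to both the cluster and its flank. Bookends on
different scaffolds mean the array is not contiguously assembled and the
species is skipped, not failed; `clip_panel()` guarantees every species
ends in exactly one of profiled / skipped:different-scaffold /
skipped:missing-bookend. Ortholog coordinates are a required input table
rather than a live database lookup, which keeps runs reproducible.
`partition_features()` produces merged genic / intergenic / exonic /
intronic / CDS / promoter interval sets (promoters only for genes with an
annotated 5′ UTR, matching the false-TSS precaution for promoter analyses);
genic + intergenic tile the region to the base pair, as do exonic +
intronic within genes. Clusters whose paralog count exceeds 3× the panel
median are flagged for inspection but never dropped automatically — no
principled automatic outlier rule exists for assembly artefacts.

## Phylogenetic regression

`pgls()` is a standard formula-interface model fit returning a classed S3
object. The covariance is the Brownian matrix of shared root-to-tip path
lengths with off-diagonals multiplied by Pagel's λ; for fixed λ the GLS
estimate is $\hat\beta = (X^{\top}C^{-1}X)^{-1}X^{\top}C^{-1}y$ with ML
$\hat\sigma^2 = r^{\top}C^{-1}r/n$, and λ maximizes the profile
log-likelihood over [0, 1] (grid at 0.01, then bounded local refinement).
Estimation is ML to match the stated estimation target, with REML available
by flag. Slope p-values use a t statistic on $n - p$ degrees of freedom
(SEs from $r^{\top}C^{-1}r/(n-p)$). $R^2$ under GLS has no unique
definition; the package reports $1 - \mathrm{RSS}_{GLS}/\mathrm{TSS}_{GLS}$
with the total SS taken about the GLS mean (an intercept-only fit at the
same λ), and documents this choice. Responses are GC fractions regressed
directly, without a logit transform, because the cross-species GC range in
these arrays is narrow and far from the boundaries. Useful invariants: a
star phylogeny reduces the fit to OLS; rescaling all branch lengths leaves
$\hat\beta$, $\hat\lambda$ and p unchanged (σ² rescales); tips at zero
patristic distance are rejected by name (singular covariance).

```{r pgls-example, eval = FALSE}
tr <- ape::rcoal(64)
pan <- simulate_species_panel(tr, b = -0.02, seed = 1)
fit <- pgls(cluster_gc ~ log_paralog, pan$table, tr)
summary(fit)
```

## What the synthetic generator does and does not emulate

`make_genome()` draws i.i.d. bases per block at the block's target GC and
then thins CpG dinucleotides by composition-preserving CG→GC swaps,
iterating toward the target CpG count because each swap can create a fresh
CpG at its boundary. This reproduces the two first-order properties the
pipeline measures — a blockwise GC mosaic spanning the realistic ~30–70%
range and a controllable CpG deficit — and is analytically checkable
(per-block GC converges at the binomial rate). `plant_genes()` places
non-overlapping gene models with exon/intron structure inside chosen blocks
and splices in promoters synthesized to a requested CpG observed/expected
(thinning when over target, planting CGs when under; the suite verifies the
achieved mean within ±0.15). `simulate_events()` makes DNMs per-site
Bernoulli with a CpG multiplier, and crossovers/PRDM9 peaks blockwise
Poisson with intensity ∝ exp(slope · block GC); crossovers are emitted as
1-kb refined intervals with i.i.d. sex labels (maternal fraction 0.5), and
a base crossover intensity of 1e-4 per bp supplies the proportionality
constant the log-linear form needs. `simulate_species_panel()` evolves log
paralog count by Brownian motion on a supplied tree (root state log 20,
typical of mid-size tandem arrays) and sets cluster GC =
a + b·log(paralogs) plus a λ-transformed Brownian residual. The effect size
b is deliberately a free parameter with a modest default (−0.02 GC per
e-fold paralogs): no quantitative estimate of how much AT content rises per
added paralog is established, so the generator does not pretend one.

Not emulated: repeat elements and LINE density, centromeres and
chromosome-scale structure, codon usage, replication timing, and any
linkage between the mutation and recombination processes beyond their
shared dependence on block GC. Passing tests therefore demonstrate that the
*algorithms* recover planted structure under the stated statistical model —
not that real genomes satisfy that model.

## Problem sizes and tolerances in the shipped checks

The test suite and `scripts/acceptance.R` use sizes chosen to make the
statistical checks decisive at desk scale: 100 synthetic mosaics
(20–30 kb blocks, ≥ 10-point GC contrast) for breakpoint recovery within
±2 kb; 100 random genes against per-base counting oracles (partition
identities at 1e-12); a 900-gene three-class trajectory mixture (ARI ≥
0.8); ≥ 500 simulated DNMs for the CpG-multiplier check (within 3 SE on the
log rate ratio); and 200 simulated 64-tip panels for PGLS slope coverage
(≥ 93% within 2 SE) plus 200 permutation fits for p-value calibration
(Kolmogorov–Smirnov against uniform). Exact identities — Shannon H of
reference compositions, the crossover normalization identity, interval
partitions — are asserted exactly or at 1e-9.

## Known limitations

- One transcript per gene (MANE-style semantics); no isoform handling.
- The segmentation halting constant is calibrated to isochore-scale
  resolution, not proven identical to any particular published segmenter;
  `t0` is exposed for other resolutions.
- Compartment consensus assumes two states (A/B); sub-compartments are out
  of scope.
- `dnm_density()` and `prdm9_enrichment()` attribute genes to isochores by
  TSS, so genes spanning an isochore boundary contribute their whole span
  to the home isochore.
- GO-term enrichment and ortholog lookup are intentionally outside the
  package; labels and bookend coordinates are consumed as input tables.
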