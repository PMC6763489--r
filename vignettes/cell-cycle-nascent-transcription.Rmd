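---
title: "Methods: cell-cycle-resolved nascent transcription and nucleosome maturation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-cycle-resolved nascent transcription and nucleosome maturation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nascentcycle)
```

# What this package computes

NET-seq records the 3′ end of the nascent RNA attached to each engaged RNA
polymerase II, giving single-base polymerase positions genome-wide. Because
absolute polymerase numbers per cell change between strains and cell-cycle
stages, libraries are normalized against a fixed *S. pombe* cell spike-in
added at harvest. On such data this package computes, for the budding-yeast
cell cycle:

* the two-stage spike-in/depth **normalization chain**;
* **region quantification** (sense and antisense) and fold-change flagging
  at fixed thresholds;
* **RNA Pol II distribution statistics**: per-gene 5′/3′ ratios with exact
  Mann–Whitney comparison, expression-normalized metagene profiles, and a
  length-ordered log2 fold-change heatmap;
* **replication-timing classes** (genes within 4 kb of early or late
  origins) and time-course summaries across a G1 → S30 → S60 → S90 arrest
  release, including the G2/G1 dosage-buffering release step;
* **nucleosome maturation metrics** on TSS-aligned dyad profiles:
  peak/trough ratio over nucleosomes +2..+7 and linker length over the
  pairs +1/+2, +2/+3, +3/+4.

A seeded generator produces synthetic worlds and libraries with recorded
ground truth so the entire analysis runs at desk scale and every estimator
can be tested against planted parameters.

# The normalization chain

Each library records `spike_reads` (uniquely mapped spike-in reads) and
`target_reads`. The per-sample spike factor is

$$ s_i = \frac{100{,}000}{\text{spike\_reads}_i}, $$

and a shared batch depth factor rescales the mean spike-scaled wild-type
read count to 1 M:

$$ d = \frac{10^6}{\operatorname{mean}_{i \in \mathrm{WT}} (s_i \cdot \text{target\_reads}_i)}. $$

Every track value is multiplied by $s_i \cdot d$. With several wild-type
replicates the mean of their spike-scaled counts is used — symmetric and
deterministic; batch membership is an explicit input because depth
variation is a property of the sequencing run. Factors are stored in a
sidecar table and in each track's normalization log rather than being baked
invisibly into files; re-normalizing is an error, and between-gene ratios
within a sample are provably invariant.

# Quantification and differential flags

Counts are sums of normalized per-base signal over each region (strand
matching the region in sense mode, the opposite strand over the same body
in antisense mode). Positions in overlapping regions count toward every
region independently; boundaries follow the half-open convention. Fold
changes use `log2((mean_B + pc)/(mean_A + pc))` with a pseudocount
(default 1 normalized read, exposed as a parameter because real zero-count
handling is a choice, not a given). P-values come from a two-sided Welch
t-test on `log2(count + pc)` across replicates — a deliberately simple,
transparent substitute for negative-binomial machinery, clearly named as
such — with Benjamini–Hochberg q-values; flags require fold change ≥ 1.5
and q ≤ 0.05. With fewer than two replicates per side p is 1 and flags
depend on the fold change alone.

# Pol II distribution statistics

**5′/3′ ratio.** Reads in `[TSS, TSS+w)` divided by reads in
`[TTS−w, TTS)`, strand-aware. The window default is `w = 300` bp (the
figure-scale convention); a 250 bp variant also circulates in the field,
so the window is a parameter rather than a constant. Genes shorter than
`2w` would have overlapping windows and are excluded from strain-level
vectors (the count is reported); a zero 3′ window marks the gene
undefined, never an exception. The ratio is invariant under positive
scaling of the track, so it is normalization-independent by construction.

**Mann–Whitney comparison.** For small samples
(`min(n_A, n_B) ≤ 8`) the exact tie-aware null distribution of the rank
sum is computed by a subset-count dynamic program over doubled midranks;
the two-sided p is `min(1, 2·min(P(S ≤ s), P(S ≥ s)))`. Larger samples use
the normal approximation with tie and continuity corrections. The exact
path is validated against full enumeration of all relabellings for every
`n_A + n_B ≤ 12`.

**Metagene.** Each gene's region from 100 bp upstream of the TSS to
200 bp downstream of the TTS is fitted into 500 bins (the whole region
including flanks is rescaled — a literal reading of the fixed-window
convention; fixed-resolution flanks would be a straightforward variant).
Each gene's binned vector is divided by that gene's mean per-bp body
signal: "individual expression level" is interpreted as mean per-bp
signal over the body, which makes the profile exactly invariant under
per-gene rescaling (a tested property). Only genes with body length
> 500 bp enter; genes whose flanks cross a chromosome edge are excluded
(padded zeros would bias terminal bins), as are genes with zero body
signal. The 95% band is mean ± 1.96·SE across genes — deterministic;
bootstrap bands would add nothing at these gene counts.

**Heatmap.** Per gene, binned signal (default 25 bp bins) over
TSS..TSS+4 kb, `log2((mut+pc)/(WT+pc))`, rows ordered by gene length,
bins past the TTS masked.

# Replication timing and the time course

Genes are screened within 4 kb of annotated origins. The distance anchor
is the TSS — a single unambiguous point; the anchor is configurable
(midpoint as an alternative) since the gene anchor convention is not
standardized. Genes within 4 kb of both timing classes are `ambiguous`
and excluded from both classes, which keeps early/late sets disjoint.
Replicates are averaged per gene before medians because the boxplot-style
summaries describe gene-level distributions. Contrasts report mutant/WT
fold ratios of medians with Mann–Whitney p per class and timepoint, and
the within-genotype S90/G1 (G2 versus G1) ratio of medians — the
dosage-buffering release step, expected near 2 when all genes have
doubled but per-copy output was halved until G2.

# Nucleosome maturation

TSS-aligned dyad profiles average the strand-oriented window −200..+1400
bp across genes. Peak calling smooths with a centered 31 bp moving
average (reflected boundaries — preserves symmetric peak positions),
finds extrema by sign changes of the discrete derivative, prunes peaks
whose prominence is below 5% of the profile's dynamic range (Poisson
micro-wiggles on averaged profiles otherwise masquerade as peaks), anchors
the nucleosome-depleted region at the global minimum in offsets
[−150, +50], and calls the first peak downstream +1. Metrics:

* **peak/trough ratio** — mean over peaks +2..+7 of height over the mean
  of the two flanking trough heights (the symmetric choice; which trough
  to use is otherwise arbitrary);
* **linker length** — mean over pairs (+1,+2), (+2,+3), (+3,+4) of
  peak-to-peak spacing minus the canonical 147 bp nucleosome footprint
  (the subtraction convention is stated explicitly because reported
  linkers rarely say; the footprint is configurable). Spacing expansion
  is treated as linker-length change throughout.

Comparisons across chase timepoints report mean ± SD per (genotype,
state); a single timepoint yields an undefined SD rather than zero.

# The synthetic generator

The generator emulates the study designs, not the genome:

* **World**: two 400 kb chromosomes, 300 non-overlapping genes (lognormal
  lengths, median ~1.2 kb, minimum 620 bp so every gene clears the 600 bp
  ratio-eligibility bound), 20 early and 20 late origins ≥ 10 kb apart;
  30% of genes placed within 4 kb of early origins, 30% near late, the
  rest far, so planted timing classes are recoverable exactly. These
  sizes keep a full pipeline run around half a minute on one CPU while
  leaving ~90 genes per timing class for stable medians.
* **Rates**: per-gene λ lognormal with median 0.25 expected reads/bp
  (WT G1, depth 1), giving a realistically wide dynamic range and a few
  hundred reads per typical gene.
* **Shape**: a fraction α = 0.4 of a gene's 3′-end reads fall uniformly
  in its first 300 bp, the remainder uniformly over the rest — a
  two-segment caricature of promoter-proximal polymerase enrichment.
  Genes not longer than 300 bp collapse to uniform (documented, not an
  error).
* **Cell cycle**: copy number doubles behind the fork (early genes by
  S30, late by S60, all by S90; far genes split between S60 and S90).
  Wild-type transcription is dosage-buffered: per-copy rates halve on
  doubling so totals stay flat, and the buffer releases at S90 where
  totals double.
* **Genotypes**: an assembly-delay mutant multiplies expression by a
  transient fold exactly where a locus has just replicated (default 8×
  for early genes at S30, 10.5× for late at S60), on sense and antisense
  alike; an acetylation-defect mutant applies a global 0.6× and scales α
  by 0.625 so the planted 5′/3′ ratio halves. Antisense transcription
  runs at 5% of sense — a free parameter, since no quantitative antisense
  rate is established.
* **Spike-in and depth**: each library carries a lognormal depth factor
  (σ = 0.15) scaling target and spike reads together;
  `spike_reads ~ Poisson(100,000 × factor)`. This is the variation the
  normalization chain is designed to remove — drawing spike reads
  independently would inject unremovable noise and emulate nothing real.
* **Nucleosomes**: dyads at TSS+60 + k·r for k = 0..7 with Gaussian
  jitter, Poisson counts thinned by occupancy; mature chromatin
  (r = 160, σ = 20, occupancy 0.9) versus nascent (r = 167, σ = 35,
  occupancy 0.6), i.e. planted linkers of 13 versus 20 bp. Chase
  timepoints interpolate nascent toward mature parameters; the
  assembly-delay genotype interpolates half as fast.

What the generator does **not** emulate: mappability and alignment
artifacts, overlapping transcription units, sequence-dependent
nucleosome positioning, fork-progression geometry beyond the dosage
schedule, or negative-binomial overdispersion beyond Poisson-plus-depth
noise. Passing recovery tests therefore demonstrate estimator
correctness under the stated model, not robustness to every property of
real libraries.

# Numerical choices and degenerate inputs

Internal coordinates are 0-based half-open everywhere; the TSS of a
minus-strand gene is `end − 1`. bedGraph is the interchange format, with
run-length-merged, lexicographically ordered output so identical tracks
are byte-identical on disk. Chromosome names pass through verbatim.
Samples with non-positive spike counts are not normalizable (error);
re-normalization is rejected; empty origin sets classify every gene
`unclassified`; a flat profile raises a typed `noPeaks` error; a missing
trough drops that peak from the ratio average (logged) rather than
failing; negative linkers are reported with a warning since they flag a
mis-called array. All generators take an explicit seed and save/restore
the global RNG state.

# Running the pipeline

```{r, eval = FALSE}
cfg <- default_run_config()          # study-stated defaults throughout
report <- run_pipeline(cfg, out_dir = "results/run", seed = 1)
```

The run report lists parameters, per-filter exclusion counts and md5
checksums of every output; reruns with identical (config, seed) are
byte-identical. The numbered scripts under `analysis/` walk the same
stages one at a time with narrative output, and `scripts/acceptance.R`
recomputes the headline quantities from scratch into a JSON file.

# Known limitations

The Welch-on-log test is underpowered at two replicates relative to
count-model tests; regulated-gene counts at default depth undercount
moderate fold changes (the thresholds and flag semantics, not the count
power, are the tested contract). The peak/trough ratio on synthetic
profiles is much larger than on real chromatin because the simulation
has no background nucleosome density between phased arrays; only
orderings and differences of this metric are meaningful across states.
Exact Mann–Whitney enumeration is limited to small samples by design;
larger samples use the corrected normal approximation, which the tests
bound against enumeration at the crossover sizes.
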