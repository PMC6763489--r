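# nascentcycle

Cell-cycle-resolved nascent transcription (NET-seq) and nucleosome
maturation analysis for budding yeast, with a seeded synthetic-data
generator that makes the whole pipeline testable at desk scale.

## The problem

NET-seq sequences the 3′ end of the RNA still attached to each engaged
RNA polymerase II, so a library is a genome-wide, single-base map of
transcribing polymerases. Two questions drive the analyses here:

1. **Is transcription buffered against gene dosage in S phase?** DNA
   replication doubles a gene's copy number mid-cycle, yet total
   transcript output stays flat until G2. Comparing spike-in-normalized
   nascent counts across a synchronized release (G1 → early S → late S →
   G2) for genes near early- versus late-firing replication origins
   resolves when each class doubles and when the buffer releases.
2. **How fast does chromatin mature behind the fork?** On newly
   replicated DNA, nucleosome arrays are initially poorly positioned and
   more widely spaced. TSS-aligned dyad profiles quantify this via the
   peak/trough ratio of nucleosomes +2..+7 and the linker length between
   nucleosomes +1/+2, +2/+3, +3/+4 (peak spacing − 147 bp footprint).

## The core computations

* **Spike-in normalization**: per-sample factor `100,000 / spike_reads`,
  then a batch factor scaling mean spike-scaled wild-type counts to 1 M
  reads; both recorded on every track.
* **Quantification**: counts = sums of normalized per-base 3′-end signal
  over regions, sense or antisense; fold changes with BH-FDR flags at
  ≥ 1.5 FC, FDR ≤ 0.05.
* **Pol II distribution**: 5′/3′ ratio (300 bp TSS window over 300 bp TTS
  window) with exact tie-aware Mann–Whitney comparison;
  expression-normalized 500-bin metagene; length-ordered log2 fold-change
  heatmap over TSS..TSS+4 kb.
* **Replication timing**: genes within 4 kb of early/late origins;
  per-class time-course medians, mutant/WT fold ratios, and the G2/G1
  buffering-release step.
* **Nucleosome maturation**: TSS-aligned dyad profiles, prominence-pruned
  peak calling anchored at the NDR, peak/trough and linker metrics,
  nascent-versus-mature comparisons across chase timepoints.

The generator plants all of this as ground truth — rates, 5′ enrichment,
dosage schedules, genotype fold effects, nucleosome geometry — so every
estimator is tested by parameter recovery. See the methods vignette
(`vignettes/cell-cycle-nascent-transcription.Rmd`) for the model and
every default.

## Worked example

```r
library(nascentcycle)

world <- simulate_world(world_config(), seed = 1)       # 300 genes, 40 origins
wt_g1  <- simulate_netseq_library(world, list(genotype = "WT", timepoint = "G1",  replicate = 1), seed = 2)
wt_g2  <- simulate_netseq_library(world, list(genotype = "WT", timepoint = "S90", replicate = 1), seed = 3)
nb     <- normalize_batch(list(wt_g1, wt_g2))
counts <- quantify_samples(nb$samples, world$genes, "sense")
classes <- classify_genes(world$genes, world$origins)
buffering_step(counts, classes)
#>   class   n    ratio
#> 1   all 300 1.971389
#> 2 early  90 2.018458
#> 3  late  90 2.074543
```

The ~2-fold S90/G1 ratio is the release of dosage buffering: every gene
has doubled by G2 while totals were held at G1 levels through S phase.
The full pipeline (all genotypes, timepoints, profiles and nucleosome
metrics) runs from one config:

```r
report <- run_pipeline(default_run_config(), out_dir = "results/run", seed = 1)
```

or stage by stage with narrative output:

```sh
Rscript analysis/01_simulate.R 1
Rscript analysis/02_normalize.R
Rscript analysis/03_quantify_diff.R
Rscript analysis/04_polii_profiles.R
Rscript analysis/05_replication_timing.R
Rscript analysis/06_nucleosome_maturation.R 1
```

which prints, for seed 1:

```
asf1-like/WT fold at early genes: G1 1.07, S30 8.04, S60 0.99, S90 0.99
asf1-like/WT fold at late genes:  G1 0.99, S30 0.99, S60 10.34, S90 1.03
WT G2/G1 step (dosage-buffering release): 2.02-fold (all genes)
5'/3' ratio medians: WT 1.991, mutant 1.002 (1.99-fold decrease), MW p = 1.3e-45
WT linkers: mature 12.7 bp, nascent (first chase point) 21.7 bp
```

— the transient S-phase derepression exactly where each gene class has
just replicated, the twofold 5′/3′ shift in the acetylation mutant, and
the wider nucleosome spacing on nascent chromatin.

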