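#!/usr/bin/env Rscript
# Stage 2: spike-in + depth normalization.
#
# Applies the two-stage chain: each library is scaled so its spike-in
# (S. pombe) reads hit 100,000, then the whole batch is scaled so the
# mean spike-scaled WT read count hits 1 M. Factors are written to a
# sidecar table for audit; normalized tracks are written per sample.

suppressMessages(library(nascentcycle))

data_dir <- "results/data"
norm_dir <- "results/normalized"
dir.create(norm_dir, recursive = TRUE, showWarnings = FALSE)

cs <- read_chrom_sizes(file.path(data_dir, "world", "chrom.sizes"))
sheet <- read_sample_sheet(file.path(data_dir, "sample_sheet.tsv"))
samples <- load_samples(sheet, cs, dir = data_dir)

nb <- normalize_batch(samples, reference_genotype = "WT")
data.table::fwrite(nb$factors, file.path(norm_dir, "scale_factors.tsv"), sep = "\t")
for (s in nb$samples) {
  write_signal_track(s$track,
                     file.path(norm_dir, paste0(s$sample_id, ".plus.bedgraph")),
                     file.path(norm_dir, paste0(s$sample_id, ".minus.bedgraph")))
}
cat(sprintf("normalized %d libraries; composite factors %.3g-%.3g (depth factor %.4g)\n",
            nrow(nb$factors), min(nb$factors$composite), max(nb$factors$composite),
            nb$factors$depth_factor[1]))
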