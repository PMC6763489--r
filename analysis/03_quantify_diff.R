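#!/usr/bin/env Rscript
# Stage 3: region quantification and differential calls.
#
# Sums normalized 3'-end signal over each annotated gene (sense and
# antisense) for every library, then flags regulated genes in the
# global-decrease mutant versus WT in G1 at the fixed thresholds
# (fold change >= 1.5, BH FDR <= 0.05; Welch t on log2 counts across
# replicates as the documented simple test).

suppressMessages(library(nascentcycle))

data_dir <- "results/data"
norm_dir <- "results/normalized"
out_dir <- "results/quantify"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cs <- read_chrom_sizes(file.path(data_dir, "world", "chrom.sizes"))
genes <- read_gene_annotation(file.path(data_dir, "world", "genes.bed"), "BED6")
sheet <- read_sample_sheet(file.path(data_dir, "sample_sheet.tsv"))
sheet$track_plus <- paste0(sheet$sample_id, ".plus.bedgraph")
sheet$track_minus <- paste0(sheet$sample_id, ".minus.bedgraph")
samples <- load_samples(sheet, cs, dir = norm_dir)

for (mode in c("sense", "antisense")) {
  counts <- quantify_samples(samples, genes, mode)
  data.table::fwrite(counts, file.path(out_dir, paste0("counts_", mode, ".tsv")),
                     sep = "\t")
}

counts <- utils::read.delim(file.path(out_dir, "counts_sense.tsv"))
wide <- function(geno) {
  sub <- counts[counts$genotype == geno & counts$timepoint == "G1", ]
  tapply(sub$count, list(sub$region_id, sub$replicate), sum)
}
fc <- fold_change_table(wide("WT"), wide("rtt109"))
data.table::fwrite(fc, file.path(out_dir, "fold_change_G1_rtt109.tsv"), sep = "\t")
reg <- count_regulated(fc)
cat(sprintf("rtt109-like vs WT in G1: %d up, %d down of %d genes (>=1.5 FC, FDR <= 0.05)\n",
            reg["n_up"], reg["n_down"], nrow(fc)))
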