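#!/usr/bin/env Rscript
# Stage 4: RNA Pol II distribution statistics.
#
# On replicate-merged normalized G1 tracks: per-gene 5'/3' ratios (TSS
# window sum over TTS window sum, 300 bp) compared between strains by
# Mann-Whitney; expression-normalized 500-bin metagene profiles; and the
# length-ordered log2 fold-change heatmap over TSS..TSS+4 kb.

suppressMessages(library(nascentcycle))

data_dir <- "results/data"
norm_dir <- "results/normalized"
out_dir <- "results/profiles"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cs <- read_chrom_sizes(file.path(data_dir, "world", "chrom.sizes"))
genes <- read_gene_annotation(file.path(data_dir, "world", "genes.bed"), "BED6")

merged_track <- function(geno) {
  merge_tracks(lapply(1:2, function(r) {
    read_signal_track(file.path(norm_dir, sprintf("%s_G1_rep%d.plus.bedgraph", geno, r)),
                      file.path(norm_dir, sprintf("%s_G1_rep%d.minus.bedgraph", geno, r)),
                      cs)
  }))
}
tracks <- lapply(c(WT = "WT", rtt109 = "rtt109"), merged_track)

ratios <- lapply(tracks, five_three_ratios, genes = genes)
rt <- do.call(rbind, lapply(names(ratios), function(g) {
  data.frame(genotype = g, gene = names(ratios[[g]]), ratio = as.numeric(ratios[[g]]))
}))
data.table::fwrite(rt, file.path(out_dir, "five_three_ratios.tsv"), sep = "\t")
cmp <- ratio_compare(ratios$rtt109, ratios$WT)
cat(sprintf("5'/3' ratio medians: WT %.3f, mutant %.3f (%.2f-fold decrease), MW p = %.3g\n",
            median(ratios$WT), median(ratios$rtt109),
            median(ratios$WT) / median(ratios$rtt109), cmp$p))

for (g in names(tracks)) {
  mg <- metagene(tracks[[g]], genes)
  data.table::fwrite(mg, file.path(out_dir, sprintf("metagene_%s.tsv", g)), sep = "\t")
}
hm <- heatmap_matrix(tracks$WT, tracks$rtt109, genes)
hm_df <- data.frame(gene = rownames(hm), length = as.numeric(attr(hm, "gene_length")), hm)
data.table::fwrite(hm_df, file.path(out_dir, "heatmap_log2fc.tsv"), sep = "\t")
cat(sprintf("metagene over %d genes; heatmap %d genes x %d bins\n",
            attr(metagene(tracks$WT, genes), "n_genes"), nrow(hm), ncol(hm)))
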