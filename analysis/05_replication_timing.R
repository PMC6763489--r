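#!/usr/bin/env Rscript
# Stage 5: replication-timing classes and the release time course.
#
# Screens genes within 4 kb of early/late origins, then summarizes
# normalized counts per class across G1/S30/S60/S90 for each genotype:
# mutant-vs-WT fold ratios with Mann-Whitney p (sense and antisense) and
# the WT G2/G1 dosage-buffering release step.

suppressMessages(library(nascentcycle))

data_dir <- "results/data"
out_dir <- "results/timing"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

genes <- read_gene_annotation(file.path(data_dir, "world", "genes.bed"), "BED6")
origins <- read_origin_annotation(file.path(data_dir, "world", "origins.bed"))
classes <- classify_genes(genes, origins)
data.table::fwrite(classes, file.path(out_dir, "classes.tsv"), sep = "\t")
cat(sprintf("screened %d genes within 4 kb of origins: %d early, %d late (%d ambiguous)\n",
            sum(classes$class != "unclassified"), sum(classes$class == "early"),
            sum(classes$class == "late"), sum(classes$class == "ambiguous")))

for (mode in c("sense", "antisense")) {
  counts <- utils::read.delim(file.path("results/quantify", paste0("counts_", mode, ".tsv")))
  tc <- timecourse_summary(counts, classes, reference_genotype = "WT")
  data.table::fwrite(tc$summary, file.path(out_dir, paste0("summary_", mode, ".tsv")), sep = "\t")
  data.table::fwrite(tc$contrasts, file.path(out_dir, paste0("contrasts_", mode, ".tsv")), sep = "\t")
}

counts <- utils::read.delim("results/quantify/counts_sense.tsv")
cc <- utils::read.delim(file.path(out_dir, "contrasts_sense.tsv"))
pick <- function(cls, tp) cc$fold_ratio[cc$class == cls & cc$genotype == "asf1" &
                                        cc$contrast == paste0(tp, "_vs_WT")]
cat(sprintf("asf1-like/WT fold at early genes: G1 %.2f, S30 %.2f, S60 %.2f, S90 %.2f\n",
            pick("early", "G1"), pick("early", "S30"), pick("early", "S60"), pick("early", "S90")))
cat(sprintf("asf1-like/WT fold at late genes:  G1 %.2f, S30 %.2f, S60 %.2f, S90 %.2f\n",
            pick("late", "G1"), pick("late", "S30"), pick("late", "S60"), pick("late", "S90")))

b <- buffering_step(counts[counts$genotype == "WT", ], classes)
data.table::fwrite(b, file.path(out_dir, "buffering_step.tsv"), sep = "\t")
cat(sprintf("WT G2/G1 step (dosage-buffering release): %.2f-fold (all genes)\n",
            b$ratio[b$class == "all"]))
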