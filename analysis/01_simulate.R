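#!/usr/bin/env Rscript
# Stage 1: build the synthetic study.
#
# Generates the default synthetic world (two 400 kb chromosomes, 300
# genes placed relative to early/late replication origins with recorded
# ground truth) and NET-seq-like libraries for WT, an assembly-factor
# mutant (asf1-like: transient fold increases where loci have just
# replicated) and an acetylation mutant (rtt109-like: global decrease
# plus reduced 5' enrichment), over the G1/S30/S60/S90 release course,
# two replicates each.

suppressMessages(library(nascentcycle))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1

data_dir <- "results/data"
dir.create(file.path(data_dir, "tracks"), recursive = TRUE, showWarnings = FALSE)

world <- simulate_world(world_config(), seed)
write_world(world, file.path(data_dir, "world"))
cat(sprintf("world: %d genes (%s), %d origins\n", nrow(world$genes),
            paste(names(table(world$truth$timing_class)),
                  table(world$truth$timing_class), collapse = " ", sep = "="),
            nrow(world$origins)))

grid <- expand.grid(replicate = 1:2, timepoint = c("G1", "S30", "S60", "S90"),
                    genotype = c("WT", "asf1", "rtt109"), stringsAsFactors = FALSE)
rows <- lapply(seq_len(nrow(grid)), function(i) {
  s <- simulate_netseq_library(world, as.list(grid[i, ]), seed = seed + 1000L * i)
  write_signal_track(s$track,
                     file.path(data_dir, "tracks", paste0(s$sample_id, ".plus.bedgraph")),
                     file.path(data_dir, "tracks", paste0(s$sample_id, ".minus.bedgraph")))
  data.frame(sample_id = s$sample_id, genotype = s$genotype, timepoint = s$timepoint,
             replicate = s$replicate, spike_reads = s$spike_reads,
             target_reads = s$target_reads,
             track_plus = paste0("tracks/", s$sample_id, ".plus.bedgraph"),
             track_minus = paste0("tracks/", s$sample_id, ".minus.bedgraph"))
})
sheet <- do.call(rbind, rows)
write_sample_sheet(sheet, file.path(data_dir, "sample_sheet.tsv"))
cat(sprintf("simulated %d libraries, %.2g total target reads; sheet at %s\n",
            nrow(sheet), sum(sheet$target_reads),
            file.path(data_dir, "sample_sheet.tsv")))
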