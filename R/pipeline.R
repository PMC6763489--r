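#' Default run configuration
#'
#' Every parameter defaults to the study-stated value where one exists:
#' 300 bp 5'/3' windows, 4 kb origin screening window, 500 metagene bins
#' with 100/200 bp flanks, fold-change threshold 1.5 at FDR 0.05, spike
#' scaling target 100,000 reads and batch depth target 1 M reads, 147 bp
#' nucleosome footprint. The synthetic design covers genotypes WT and
#' asf1 over the G1/S30/S60/S90 release time course with two replicates.
#'
#' @param ... overrides for any field (the `world` field takes a
#'   [world_config()]).
#' @return a named list of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    seed = 1,
    world = world_config(),
    inputs = NULL,                 # optional: list(genes, origins, chrom_sizes, sample_sheet)
    stages = c("simulate", "normalize", "quantify", "diff", "profile",
               "timing", "nucleosome"),
    genotypes = c("WT", "asf1", "rtt109"),
    mutant = "asf1",
    timepoints = c("G1", "S30", "S60", "S90"),
    replicates = 2,
    depth = 1,
    reference_genotype = "WT",
    spike_target = 1e5,
    depth_target = 1e6,
    fc_threshold = 1.5,
    fdr_threshold = 0.05,
    pseudocount = 1,
    ratio_window = 300,
    metagene_bins = 500,
    flank_up = 100,
    flank_down = 200,
    heatmap_span = 4000,
    heatmap_bin = 25,
    origin_window = 4000,
    anchor = "tss",
    nucleosome_depth = 20,
    nucleosome_chase = c(0, 0.8),  # fraction matured at each chase timepoint
    smooth_width = 31,
    footprint = 147,
    profile_genotypes = c("WT", "rtt109")
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Keys override [default_run_config()]; keys under `world` override
#' [world_config()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  world_over <- raw$world %||% list()
  raw$world <- NULL
  cfg <- do.call(default_run_config, raw)
  cfg$world <- do.call(world_config, world_over)
  cfg
}

interp_state <- function(nascent, mature, f) {
  list(repeat_length = nascent$repeat_length + f * (mature$repeat_length - nascent$repeat_length),
       jitter = nascent$jitter + f * (mature$jitter - nascent$jitter),
       occupancy = nascent$occupancy + f * (mature$occupancy - nascent$occupancy))
}

#' Average several normalized tracks (replicate merging)
#' @param tracks list of [signal_track]s on identical chromosomes.
#' @return a [signal_track] with the per-base mean.
#' @export
merge_tracks <- function(tracks) {
  out <- tracks[[1]]
  for (ch in names(out$chrom_sizes)) {
    out$plus[[ch]] <- Reduce(`+`, lapply(tracks, function(t) t$plus[[ch]])) / length(tracks)
    out$minus[[ch]] <- Reduce(`+`, lapply(tracks, function(t) t$minus[[ch]])) / length(tracks)
  }
  out
}

tsv <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t", eol = "\n")
  path
}

#' Run the full synthetic pipeline from one configuration
#'
#' Orchestrates simulate, normalize, quantify, diff, profile, timing and
#' nucleosome stages from a single config and seed, writing every stage
#' output under `out_dir` plus a machine-readable `report.yaml` with the
#' parameters, per-filter exclusion counts and md5 checksums of all
#' outputs. Reruns with identical (config, seed) are byte-identical. Any
#' stage error aborts with the stage named.
#'
#' @param config a `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @param out_dir output directory.
#' @param seed overrides `config$seed` when given.
#' @return the report, invisibly (also written to
#'   `file.path(out_dir, "report.yaml")`).
#' @export
run_pipeline <- function(config = default_run_config(), out_dir, seed = NULL) {
  seed <- as.integer(seed %||% config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  exclusions <- list()
  stage <- function(name, expr) {
    if (!name %in% config$stages) return(NULL)
    tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  emit <- function(path) { outputs <<- c(outputs, path); path }

  ## -- simulate ------------------------------------------------------------
  world <- NULL; samples_raw <- NULL
  stage("simulate", {
    if (is.null(config$inputs)) {
      world <- simulate_world(config$world, seed)
      wd <- file.path(out_dir, "world")
      write_world(world, wd)
      for (f in c("genes.bed", "origins.bed", "truth.tsv", "chrom.sizes")) {
        emit(file.path(wd, f))
      }
      grid <- expand.grid(replicate = seq_len(config$replicates),
                          timepoint = config$timepoints,
                          genotype = config$genotypes,
                          stringsAsFactors = FALSE)
      samples_raw <- lapply(seq_len(nrow(grid)), function(i) {
        spec <- as.list(grid[i, ])
        simulate_netseq_library(world, spec, depth = config$depth,
                                seed = seed + 1000L * i)
      })
      sheet <- do.call(rbind, lapply(samples_raw, function(s) {
        data.frame(sample_id = s$sample_id, genotype = s$genotype,
                   timepoint = s$timepoint, replicate = s$replicate,
                   spike_reads = s$spike_reads, target_reads = s$target_reads,
                   track_plus = paste0(s$sample_id, ".plus.bedgraph"),
                   track_minus = paste0(s$sample_id, ".minus.bedgraph"))
      }))
      td <- file.path(out_dir, "tracks")
      dir.create(td, showWarnings = FALSE)
      for (s in samples_raw) {
        write_signal_track(s$track,
                           emit(file.path(td, paste0(s$sample_id, ".plus.bedgraph"))),
                           emit(file.path(td, paste0(s$sample_id, ".minus.bedgraph"))))
      }
      emit(tsv(sheet, file.path(out_dir, "sample_sheet.tsv")))
    } else {
      cs <- read_chrom_sizes(config$inputs$chrom_sizes)
      genes <- read_gene_annotation(config$inputs$genes, config$inputs$genes_format %||% "BED6")
      sheet <- read_sample_sheet(config$inputs$sample_sheet)
      samples_raw <- load_samples(sheet, cs, dirname(config$inputs$sample_sheet))
      world <- list(genes = genes, origins = NULL,
                     config = world_config(chrom_sizes = cs))
      if (!is.null(config$inputs$origins)) {
        world$origins <- read_origin_annotation(config$inputs$origins)
      }
    }
  })

  ## -- normalize -----------------------------------------------------------
  samples <- NULL
  stage("normalize", {
    nb <- normalize_batch(samples_raw, config$reference_genotype,
                          config$depth_target, config$spike_target)
    samples <- nb$samples
    emit(tsv(nb$factors, file.path(out_dir, "scale_factors.tsv")))
  })

  ## -- quantify ------------------------------------------------------------
  counts_sense <- NULL; counts_anti <- NULL
  stage("quantify", {
    counts_sense <- quantify_samples(samples, world$genes, "sense")
    counts_anti <- quantify_samples(samples, world$genes, "antisense")
    emit(tsv(counts_sense, file.path(out_dir, "counts_sense.tsv")))
    emit(tsv(counts_anti, file.path(out_dir, "counts_antisense.tsv")))
  })

  ## -- diff (mutant vs reference at G1) ------------------------------------
  stage("diff", {
    wide <- function(geno) {
      sub <- counts_sense[counts_sense$genotype == geno &
                          counts_sense$timepoint == config$timepoints[1], ]
      m <- tapply(sub$count, list(sub$region_id, sub$replicate), sum)
      m[world$genes$id, , drop = FALSE]
    }
    fc <- fold_change_table(wide(config$reference_genotype), wide(config$mutant),
                            config$pseudocount, config$fc_threshold,
                            config$fdr_threshold)
    emit(tsv(fc, file.path(out_dir, "fold_change_G1.tsv")))
    reg <- count_regulated(fc, config$fc_threshold, config$fdr_threshold)
    emit(tsv(data.frame(direction = names(reg), n = as.integer(reg)),
             file.path(out_dir, "regulated_counts.tsv")))
  })

  ## -- profile -------------------------------------------------------------
  stage("profile", {
    gts <- intersect(config$profile_genotypes, config$genotypes)
    if (length(gts) < 2L) gts <- config$genotypes[1:2]
    merged <- lapply(gts, function(g) {
      reps <- Filter(function(s) s$genotype == g &&
                       s$timepoint == config$timepoints[1], samples)
      merge_tracks(lapply(reps, `[[`, "track"))
    })
    names(merged) <- gts
    rl <- lapply(merged, five_three_ratios, genes = world$genes,
                 window = config$ratio_window)
    rt <- do.call(rbind, lapply(gts, function(g) {
      data.frame(genotype = g, gene = names(rl[[g]]), ratio = as.numeric(rl[[g]]))
    }))
    emit(tsv(rt, file.path(out_dir, "five_three_ratios.tsv")))
    cmp <- ratio_compare(rl[[gts[2]]], rl[[gts[1]]])
    emit(tsv(data.frame(contrast = paste0(gts[2], "_vs_", gts[1]),
                        median_A = median(rl[[gts[1]]]),
                        median_B = median(rl[[gts[2]]]),
                        U = cmp$U, p = cmp$p),
             file.path(out_dir, "ratio_comparison.tsv")))
    exclusions$ratio_short <- attr(rl[[1]], "n_short")
    exclusions$ratio_undefined <- attr(rl[[1]], "n_undefined")
    for (g in gts) {
      mg <- metagene(merged[[g]], world$genes, config$metagene_bins,
                     config$flank_up, config$flank_down)
      emit(tsv(mg, file.path(out_dir, sprintf("metagene_%s.tsv", g))))
      exclusions[[paste0("metagene_zero_", g)]] <- attr(mg, "n_excluded_zero")
      exclusions[[paste0("metagene_edge_", g)]] <- attr(mg, "n_excluded_edge")
    }
    hm <- heatmap_matrix(merged[[gts[1]]], merged[[gts[2]]], world$genes,
                         config$heatmap_span, config$heatmap_bin,
                         config$pseudocount)
    hm_df <- data.frame(gene = rownames(hm),
                        length = as.numeric(attr(hm, "gene_length")), hm,
                        check.names = FALSE)
    names(hm_df) <- c("gene", "length",
                      sprintf("bin%03d", seq_len(ncol(hm))))
    emit(tsv(hm_df, file.path(out_dir, "heatmap_log2fc.tsv")))
  })

  ## -- timing --------------------------------------------------------------
  stage("timing", {
    if (is.null(world$origins) || nrow(world$origins) == 0L) {
      stop("no origin annotation available")
    }
    classes <- classify_genes(world$genes, world$origins,
                              config$origin_window, config$anchor)
    emit(tsv(classes, file.path(out_dir, "timing_classes.tsv")))
    tc <- timecourse_summary(counts_sense, classes, config$reference_genotype)
    emit(tsv(tc$summary, file.path(out_dir, "timecourse_summary.tsv")))
    emit(tsv(tc$contrasts, file.path(out_dir, "timecourse_contrasts.tsv")))
    tca <- timecourse_summary(counts_anti, classes, config$reference_genotype)
    emit(tsv(tca$summary, file.path(out_dir, "timecourse_summary_antisense.tsv")))
    emit(tsv(tca$contrasts, file.path(out_dir, "timecourse_contrasts_antisense.tsv")))
    wt <- counts_sense[counts_sense$genotype == config$reference_genotype, ]
    emit(tsv(buffering_step(wt, classes), file.path(out_dir, "buffering_step.tsv")))
  })

  ## -- nucleosome ----------------------------------------------------------
  stage("nucleosome", {
    st <- world$config$nucleosome$states
    rows <- list(); prof_acc <- list()
    for (g in c(config$reference_genotype, config$mutant)) {
      # the mutant's assembly delay: nascent chromatin matures more slowly
      chase <- if (g == config$reference_genotype) config$nucleosome_chase
               else config$nucleosome_chase / 2
      for (ti in seq_along(chase)) {
        pars <- interp_state(st$nascent, st$mature, chase[ti])
        tr <- simulate_dyad_track(world, "nascent", config$nucleosome_depth,
                                  seed + 77L * ti + ifelse(g == config$mutant, 7L, 0L),
                                  state_params = pars)
        pr <- tss_profile(tr, world$genes)
        mm <- maturation_metrics(call_peaks(pr, smooth_width = config$smooth_width),
                                 config$footprint)
        rows[[length(rows) + 1L]] <- data.frame(genotype = g, state = "nascent",
          timepoint = ti, peak_trough_ratio = mm$peak_trough_ratio,
          linker_length = mm$linker_length)
        prof_acc[[sprintf("%s_nascent_t%d", g, ti)]] <- pr
      }
      trm <- simulate_dyad_track(world, "mature", config$nucleosome_depth,
                                 seed + 991L + ifelse(g == config$mutant, 7L, 0L))
      prm <- tss_profile(trm, world$genes)
      mmm <- maturation_metrics(call_peaks(prm, smooth_width = config$smooth_width),
                                config$footprint)
      rows[[length(rows) + 1L]] <- data.frame(genotype = g, state = "mature",
        timepoint = 1L, peak_trough_ratio = mmm$peak_trough_ratio,
        linker_length = mmm$linker_length)
      prof_acc[[paste0(g, "_mature")]] <- prm
    }
    metrics <- do.call(rbind, rows)
    emit(tsv(metrics, file.path(out_dir, "nucleosome_metrics.tsv")))
    emit(tsv(compare_states(metrics), file.path(out_dir, "nucleosome_comparison.tsv")))
    pr_long <- do.call(rbind, lapply(names(prof_acc), function(nm) {
      data.frame(profile = nm, offset = prof_acc[[nm]]$offset,
                 density = prof_acc[[nm]]$density)
    }))
    emit(tsv(pr_long, file.path(out_dir, "nucleosome_profiles.tsv")))
  })

  ## -- report --------------------------------------------------------------
  checksums <- as.list(tools::md5sum(outputs))
  names(checksums) <- substring(outputs, nchar(out_dir) + 2L)
  report <- list(
    package = "nascentcycle",
    version = as.character(utils::packageVersion("nascentcycle")),
    seed = seed,
    stages = config$stages,
    parameters = config[setdiff(names(config), c("world", "inputs", "stages"))],
    world = unclass(config$world)[c("chrom_sizes", "n_genes", "frac_near_early",
                                    "frac_near_late", "n_origins_early",
                                    "n_origins_late", "lambda_meanlog", "alpha",
                                    "antisense_fraction")],
    exclusions = exclusions,
    outputs = checksums
  )
  yaml::write_yaml(report, file.path(out_dir, "report.yaml"))
  invisible(report)
}
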