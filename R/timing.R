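#' Classify genes by proximity to early/late replication origins
#'
#' The distance from each gene's anchor (TSS by default) to the nearest
#' origin of each timing class is measured; a gene within `window` bp of
#' an early origin only is `early`, of a late origin only `late`, of both
#' `ambiguous` (excluded from either class), and otherwise
#' `unclassified`. With no origins, every gene is unclassified.
#'
#' @param genes a [gene_set].
#' @param origins an `origin_set` with timing labels.
#' @param window screening distance in bp (default 4000, i.e. 4 kb
#'   upstream or downstream of an origin).
#' @param anchor `"tss"` or `"midpoint"`.
#' @return data.frame of class `timing_class`: id, class, distance
#'   (bp to the nearest origin of any timing; `Inf` with no origins).
#' @export
classify_genes <- function(genes, origins, window = 4000,
                           anchor = c("tss", "midpoint")) {
  anchor <- match.arg(anchor)
  pos <- if (anchor == "tss") tss(genes) else floor((genes$start + genes$end) / 2)
  d_to <- function(timing) {
    sub <- origins[origins$timing == timing, , drop = FALSE]
    vapply(seq_len(nrow(genes)), function(i) {
      s <- sub$chrom == genes$chrom[i]
      if (!any(s)) Inf else min(abs(sub$position[s] - pos[i]))
    }, numeric(1))
  }
  d_early <- d_to("early"); d_late <- d_to("late")
  cls <- ifelse(d_early <= window & d_late <= window, "ambiguous",
         ifelse(d_early <= window, "early",
         ifelse(d_late <= window, "late", "unclassified")))
  out <- data.frame(id = genes$id, class = cls,
                    distance = pmin(d_early, d_late), stringsAsFactors = FALSE)
  class(out) <- c("timing_class", "data.frame")
  out
}

avg_replicates <- function(counts) {
  dt <- data.table::as.data.table(counts)
  as.data.frame(dt[, list(count = mean(count)),
                   by = c("region_id", "genotype", "timepoint")])
}

#' Time-course summary of nascent transcription by timing class
#'
#' Replicates are averaged per gene first; per (class, genotype,
#' timepoint) the gene-level distribution is summarized (n, median,
#' quartiles). Contrasts report, per class and timepoint, the
#' mutant/reference fold ratio of medians with a Mann-Whitney p, and
#' within each genotype the G2-versus-G1 (S90/G1) ratio of medians.
#'
#' @param counts long counts data.frame from [quantify_samples()] (columns
#'   region_id, genotype, timepoint, replicate, count), normalized on a
#'   common batch.
#' @param classes a `timing_class` data.frame from [classify_genes()];
#'   genes are grouped by its `class` column (plus an `"all"` group).
#' @param reference_genotype genotype contrasted against (default "WT").
#' @return list of class `timecourse_summary` with data.frames `summary`
#'   (class, genotype, timepoint, n, median, q1, q3) and `contrasts`
#'   (class, genotype, contrast, fold_ratio, U, p).
#' @export
timecourse_summary <- function(counts, classes, reference_genotype = "WT") {
  avg <- avg_replicates(counts)
  avg$class <- classes$class[match(avg$region_id, classes$id)]
  groups <- c("all", setdiff(unique(classes$class), c("unclassified", "ambiguous")))
  genotypes <- unique(avg$genotype)
  tps <- intersect(timepoints_ordered, unique(avg$timepoint))
  summ <- list(); contr <- list()
  val <- function(cls, g, t) {
    s <- avg$genotype == g & avg$timepoint == t & (cls == "all" | (!is.na(avg$class) & avg$class == cls))
    setNames(avg$count[s], avg$region_id[s])
  }
  for (cls in groups) {
    n_genes <- if (cls == "all") length(unique(avg$region_id)) else sum(classes$class == cls)
    if (n_genes == 0L) {
      warning("timing class '", cls, "' has no genes; summary omitted")
      next
    }
    for (g in genotypes) for (t in tps) {
      v <- val(cls, g, t)
      if (length(v) == 0L) next
      qs <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      summ[[length(summ) + 1L]] <- data.frame(class = cls, genotype = g,
        timepoint = t, n = length(v), median = qs[2], q1 = qs[1], q3 = qs[3])
    }
    for (g in setdiff(genotypes, reference_genotype)) for (t in tps) {
      vm <- val(cls, g, t); vw <- val(cls, reference_genotype, t)
      if (length(vm) == 0L || length(vw) == 0L || median(vw) == 0) next
      mw <- mann_whitney(vm, vw)
      contr[[length(contr) + 1L]] <- data.frame(class = cls, genotype = g,
        contrast = paste0(t, "_vs_", reference_genotype),
        fold_ratio = median(vm) / median(vw), U = mw$U, p = mw$p)
    }
    if (all(c("G1", "S90") %in% tps)) {
      for (g in genotypes) {
        v1 <- val(cls, g, "G1"); v9 <- val(cls, g, "S90")
        if (length(v1) == 0L || length(v9) == 0L || median(v1) == 0) next
        mw <- mann_whitney(v9, v1)
        contr[[length(contr) + 1L]] <- data.frame(class = cls, genotype = g,
          contrast = "S90_vs_G1", fold_ratio = median(v9) / median(v1),
          U = mw$U, p = mw$p)
      }
    }
  }
  structure(list(summary = do.call(rbind, summ),
                 contrasts = do.call(rbind, contr)),
            class = "timecourse_summary")
}

#' G2/G1 stepwise-doubling (dosage-buffering release) ratio
#'
#' Ratio of the per-gene median count at S90 (G2) to the median at G1,
#' for all genes and per timing class. Replicates are averaged per gene
#' first. Under dosage buffering the expectation is ~1 through S phase
#' and ~2 at G2.
#'
#' @param counts_WT long counts data.frame for the wild type containing
#'   G1 and S90 timepoints.
#' @param classes a `timing_class` data.frame.
#' @return data.frame: class, n, ratio.
#' @export
buffering_step <- function(counts_WT, classes) {
  avg <- avg_replicates(counts_WT)
  if (!all(c("G1", "S90") %in% avg$timepoint)) {
    stop("counts must contain G1 and S90 timepoints")
  }
  avg$class <- classes$class[match(avg$region_id, classes$id)]
  groups <- c("all", setdiff(unique(classes$class), c("unclassified", "ambiguous")))
  out <- do.call(rbind, lapply(groups, function(cls) {
    s <- if (cls == "all") rep(TRUE, nrow(avg)) else (!is.na(avg$class) & avg$class == cls)
    g1 <- avg$count[s & avg$timepoint == "G1"]
    s90 <- avg$count[s & avg$timepoint == "S90"]
    if (length(g1) == 0L) return(NULL)
    m1 <- median(g1)
    if (m1 == 0) stop("zero G1 median for class '", cls, "'")
    data.frame(class = cls, n = length(g1), ratio = median(s90) / m1)
  }))
  rownames(out) <- NULL
  out
}
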