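#' Configuration for synthetic worlds
#'
#' Returns the default study-scale configuration: two 400 kb chromosomes,
#' 300 non-overlapping genes of which 30% are placed within 4 kb of
#' an early-firing replication origin, 30% within 4 kb of a
#' late-firing origin, and the rest farther than 4 kb from every origin;
#' twenty origins per timing class. Per-gene transcription rates are
#' lognormal (median 0.25 expected reads/bp in wild-type G1 at depth 1),
#' with a two-segment positional shape putting a fraction `alpha` of each
#' gene's 3'-end reads in its first `first_bp` bases. Copy number doubles
#' behind the replication fork (early genes by S30, late genes by S60, all
#' by S90) but transcription is dosage-buffered: per-copy rates halve on
#' doubling, and the buffer is released in G2 (S90) where total output
#' doubles. Genotypes are defined by a global fold (`base_fold`), transient
#' fold multipliers applied where a locus has just replicated
#' (`fold_early_s30`, `fold_late_s60`), and a scaling of the 5' enrichment
#' (`alpha_scale`). Nucleosome chromatin states map to (repeat length bp,
#' dyad jitter SD bp, occupancy fraction).
#'
#' @param ... overrides for any default field.
#' @return a named list of class `world_config`.
#' @export
world_config <- function(...) {
  cfg <- list(
    chrom_sizes = c(chrI = 400000, chrII = 400000),
    n_genes = 300,
    frac_near_early = 0.3,
    frac_near_late = 0.3,
    n_origins_early = 20,
    n_origins_late = 20,
    origin_window = 4000,
    min_origin_gap = 10000,
    edge_margin = 2000,
    gene_length_meanlog = log(1200),
    gene_length_sdlog = 0.35,
    min_gene_length = 620,
    gene_gap = 50,
    lambda_meanlog = log(0.25),
    lambda_sdlog = 0.7,
    alpha = 0.4,
    first_bp = 300,
    antisense_fraction = 0.05,
    far_s60_fraction = 0.5,
    spike_median = 100000,
    depth_sdlog = 0.15,
    genotypes = list(
      WT = list(base_fold = 1, fold_early_s30 = 1, fold_late_s60 = 1, alpha_scale = 1),
      asf1 = list(base_fold = 1, fold_early_s30 = 8, fold_late_s60 = 10.5, alpha_scale = 1),
      cac1rtt106 = list(base_fold = 1, fold_early_s30 = 25, fold_late_s60 = 13, alpha_scale = 1),
      rtt109 = list(base_fold = 0.6, fold_early_s30 = 1, fold_late_s60 = 1, alpha_scale = 0.625)
    ),
    nucleosome = list(
      plus_one_offset = 60,
      n_nucleosomes = 8,
      states = list(
        mature = list(repeat_length = 160, jitter = 20, occupancy = 0.9),
        nascent = list(repeat_length = 167, jitter = 35, occupancy = 0.6)
      )
    )
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  class(cfg) <- "world_config"
  cfg
}

timepoints_ordered <- c("G1", "S30", "S60", "S90")

place_origins <- function(cfg) {
  n <- cfg$n_origins_early + cfg$n_origins_late
  if (n == 0L) return(origin_set(character(), numeric(), character()))
  chroms <- names(cfg$chrom_sizes)
  pos <- numeric(0); chr <- character(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (att in 1:2000) {
      c_i <- sample(chroms, 1, prob = cfg$chrom_sizes)
      lim <- cfg$chrom_sizes[[c_i]]
      p_i <- sample.int(lim - 2L * cfg$edge_margin, 1) + cfg$edge_margin
      same <- chr == c_i
      if (!any(same) || min(abs(pos[same] - p_i)) >= cfg$min_origin_gap) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("infeasible packing: cannot place origins with the requested spacing")
    pos <- c(pos, p_i); chr <- c(chr, c_i)
  }
  timing <- c(rep("early", cfg$n_origins_early), rep("late", cfg$n_origins_late))
  origin_set(chr, pos, timing)
}

#' Generate a synthetic world: annotation, origins and ground truth
#'
#' Genes are placed without overlap on either strand, with a configurable
#' fraction within the origin window of early origins, of late origins,
#' and far (> window) from all origins, so the planted timing class is
#' recoverable exactly. Per-gene rates, 5'-shape, dosage schedules and
#' genotype multipliers are recorded as ground truth.
#'
#' @param config a [world_config()].
#' @param seed integer seed; identical (config, seed) gives identical output.
#' @return list of class `synthetic_world` with elements `genes`
#'   ([gene_set]), `origins` (`origin_set`), `truth` (data.frame) and
#'   `config`.
#' @export
simulate_world <- function(config = world_config(), seed = 1) {
  cfg <- config
  with_seed(seed, {
    origins <- place_origins(cfg)
    n <- cfg$n_genes
    if (n == 0L) {
      truth <- data.frame(id = character(), lambda = numeric(), alpha = numeric(),
                          timing_class = character(), d_G1 = numeric(),
                          d_S30 = numeric(), d_S60 = numeric(), d_S90 = numeric())
      world <- structure(list(genes = gene_set(character(), character(), numeric(),
                                               numeric(), character()),
                              origins = origins, truth = truth, config = cfg),
                         class = "synthetic_world")
      return(world)
    }
    n_e <- round(n * cfg$frac_near_early)
    n_l <- round(n * cfg$frac_near_late)
    classes <- c(rep("early", n_e), rep("late", n_l), rep("far", n - n_e - n_l))
    lens <- pmax(cfg$min_gene_length,
                 round(rlnorm(n, cfg$gene_length_meanlog, cfg$gene_length_sdlog)))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    early <- origins[origins$timing == "early", , drop = FALSE]
    late <- origins[origins$timing == "late", , drop = FALSE]
    w <- cfg$origin_window
    placed <- lapply(names(cfg$chrom_sizes), function(x) matrix(numeric(0), ncol = 2))
    names(placed) <- names(cfg$chrom_sizes)
    chrom <- character(n); start <- numeric(n); end <- numeric(n)
    min_dist <- function(set, ch, p) {
      s <- set$chrom == ch
      if (!any(s)) Inf else min(abs(set$position[s] - p))
    }
    for (i in seq_len(n)) {
      ok <- FALSE
      for (att in 1:1000) {
        if (classes[i] == "early" && nrow(early)) {
          o <- early[sample.int(nrow(early), 1), ]
          p <- o$position + sample.int(2L * w + 1L, 1) - w - 1L
          ch <- o$chrom
          if (min_dist(late, ch, p) <= w) next
        } else if (classes[i] == "late" && nrow(late)) {
          o <- late[sample.int(nrow(late), 1), ]
          p <- o$position + sample.int(2L * w + 1L, 1) - w - 1L
          ch <- o$chrom
          if (min_dist(early, ch, p) <= w) next
        } else {
          ch <- sample(names(cfg$chrom_sizes), 1, prob = cfg$chrom_sizes)
          p <- sample.int(cfg$chrom_sizes[[ch]], 1) - 1L
          if (min_dist(origins, ch, p) <= w) next
        }
        if (strands[i] == "+") { s0 <- p; e0 <- p + lens[i] } else { s0 <- p - lens[i] + 1; e0 <- p + 1 }
        if (s0 < cfg$edge_margin || e0 > cfg$chrom_sizes[[ch]] - cfg$edge_margin) next
        occ <- placed[[ch]]
        if (nrow(occ) && any(s0 - cfg$gene_gap < occ[, 2] & e0 + cfg$gene_gap > occ[, 1])) next
        chrom[i] <- ch; start[i] <- s0; end[i] <- e0
        placed[[ch]] <- rbind(occ, c(s0, e0))
        ok <- TRUE
        break
      }
      if (!ok) stop("infeasible packing: could not place gene ", i,
                    " without overlap under the class constraints")
    }
    ids <- sprintf("gene%04d", seq_len(n))
    genes <- gene_set(ids, chrom, start, end, strands)
    lambda <- rlnorm(n, cfg$lambda_meanlog, cfg$lambda_sdlog)
    alpha <- rep(cfg$alpha, n)
    far_s60 <- rbinom(n, 1, cfg$far_s60_fraction) == 1
    d <- t(vapply(seq_len(n), function(i) {
      switch(classes[i],
             early = c(1, 2, 2, 2),
             late = c(1, 1, 2, 2),
             far = if (far_s60[i]) c(1, 1, 2, 2) else c(1, 1, 1, 2))
    }, numeric(4)))
    truth <- data.frame(id = ids, lambda = lambda, alpha = alpha,
                        timing_class = classes,
                        d_G1 = d[, 1], d_S30 = d[, 2], d_S60 = d[, 3], d_S90 = d[, 4])
    structure(list(genes = genes, origins = origins, truth = truth, config = cfg),
              class = "synthetic_world")
  })
}

#' Expected normalized-scale read count per gene for a design cell
#'
#' The analytic expectation used by the generator: `lambda * length *
#' depth * B * m`, where the buffering term `B` is 1 before G2 (per-copy
#' rates halve when the locus doubles, so totals are flat) and equals the
#' final copy number (2) at S90, and `m` is the genotype multiplier
#' (global `base_fold`, times the transient fold where the gene's class
#' has just replicated: early genes at S30, late genes at S60).
#'
#' @param world a `synthetic_world`.
#' @param genotype name of a genotype in the world config.
#' @param timepoint `"G1"`, `"S30"`, `"S60"`, `"S90"` or `"async"`.
#' @param depth sequencing-depth multiplier.
#' @return numeric vector of expected sense read counts, one per gene.
#' @export
expected_counts <- function(world, genotype, timepoint, depth = 1) {
  cfg <- world$config
  geno <- cfg$genotypes[[genotype]]
  if (is.null(geno)) stop("unknown genotype: ", genotype)
  tr <- world$truth
  len <- world$genes$end - world$genes$start
  B <- if (timepoint == "S90") tr$d_S90 else rep(1, nrow(tr))
  m <- rep(geno$base_fold %||% 1, nrow(tr))
  if (timepoint == "S30") m <- m * ifelse(tr$timing_class == "early", geno$fold_early_s30 %||% 1, 1)
  if (timepoint == "S60") m <- m * ifelse(tr$timing_class == "late", geno$fold_late_s60 %||% 1, 1)
  tr$lambda * len * depth * B * m
}

#' Simulate one NET-seq-like library
#'
#' Per-gene sense read counts are Poisson with the [expected_counts()]
#' mean; read positions follow the two-segment shape (a fraction
#' `alpha * alpha_scale` uniform over the first `first_bp` bases of the
#' gene, the rest uniform over the remainder; genes not longer than
#' `first_bp` collapse to uniform). Antisense reads are drawn at
#' `antisense_fraction` of the sense mean, uniform over the gene body on
#' the opposite strand. Only the 3' end of each nascent RNA is recorded,
#' as a count on the [signal_track]. Sequencing-run depth varies between
#' libraries as a lognormal factor (`depth_sdlog`) that scales target and
#' spike-in reads together, which is precisely the variation the spike
#' normalization chain is designed to remove; the spike-in enters as a
#' scalar Poisson read count around `spike_median` times that factor.
#'
#' @param world a `synthetic_world`.
#' @param sample_spec list with `genotype`, `timepoint`, `replicate`
#'   (and optionally `sample_id`).
#' @param depth depth multiplier (expected reads scale linearly).
#' @param seed integer seed.
#' @return a [library_sample].
#' @export
simulate_netseq_library <- function(world, sample_spec, depth = 1, seed = 1) {
  cfg <- world$config
  geno <- cfg$genotypes[[sample_spec$genotype]]
  if (is.null(geno)) stop("unknown genotype: ", sample_spec$genotype)
  if (depth <= 0) stop("depth must be > 0")
  with_seed(seed, {
    genes <- world$genes
    depth_noise <- rlnorm(1, 0, cfg$depth_sdlog)
    mu <- expected_counts(world, sample_spec$genotype, sample_spec$timepoint,
                          depth * depth_noise)
    alpha_eff <- pmin(1, world$truth$alpha * (geno$alpha_scale %||% 1))
    track <- signal_track(cfg$chrom_sizes)
    total <- 0
    for (i in seq_len(nrow(genes))) {
      len <- genes$end[i] - genes$start[i]
      n <- rpois(1, mu[i])
      if (n > 0) {
        if (len > cfg$first_bp && alpha_eff[i] > 0) {
          n5 <- rbinom(1, n, alpha_eff[i])
          off <- c(sample.int(cfg$first_bp, n5, replace = TRUE) - 1L,
                   cfg$first_bp + sample.int(len - cfg$first_bp, n - n5, replace = TRUE) - 1L)
        } else {
          off <- sample.int(len, n, replace = TRUE) - 1L
        }
        pos <- if (genes$strand[i] == "+") genes$start[i] + off else genes$end[i] - 1 - off
        track <- add_reads(track, genes$chrom[i], pos, genes$strand[i])
        total <- total + n
      }
      na <- rpois(1, mu[i] * cfg$antisense_fraction)
      if (na > 0) {
        offa <- sample.int(len, na, replace = TRUE) - 1L
        anti <- if (genes$strand[i] == "+") "-" else "+"
        track <- add_reads(track, genes$chrom[i], genes$start[i] + offa, anti)
        total <- total + na
      }
    }
    spike <- max(1, rpois(1, cfg$spike_median * depth_noise))
    sid <- sample_spec$sample_id %||%
      sprintf("%s_%s_rep%d", sample_spec$genotype, sample_spec$timepoint,
              sample_spec$replicate %||% 1)
    library_sample(sid, sample_spec$genotype, sample_spec$timepoint,
                   sample_spec$replicate %||% 1, track, spike, total)
  })
}

#' Simulate a nucleosome dyad-density track
#'
#' For each gene, dyads are planted at `TSS + plus_one_offset + k * r`
#' (strand-oriented, k = 0..n_nucleosomes-1) with Gaussian positional
#' jitter and Poisson read counts thinned to the state's occupancy; all
#' genes are pooled into one unstranded dyad track.
#'
#' @param world a `synthetic_world`.
#' @param chromatin_state `"mature"` or `"nascent"` (looked up in the world
#'   config), or supply `state_params` directly.
#' @param depth expected dyad reads per nucleosome slot at occupancy 1.
#' @param seed integer seed.
#' @param state_params optional list(repeat_length, jitter, occupancy)
#'   overriding the configured state.
#' @return a [signal_track] (unstranded; mass on the plus arrays).
#' @export
simulate_dyad_track <- function(world, chromatin_state = "mature", depth = 20,
                                seed = 1, state_params = NULL) {
  cfg <- world$config
  st <- state_params %||% cfg$nucleosome$states[[chromatin_state]]
  if (is.null(st)) stop("unknown chromatin state: ", chromatin_state)
  if (st$repeat_length < 147) {
    stop("repeat_length must be >= 147 bp (nucleosomes would overlap)")
  }
  with_seed(seed, {
    genes <- world$genes
    track <- signal_track(cfg$chrom_sizes)
    koff <- cfg$nucleosome$plus_one_offset +
      (seq_len(cfg$nucleosome$n_nucleosomes) - 1L) * st$repeat_length
    for (i in seq_len(nrow(genes))) {
      tssp <- if (genes$strand[i] == "+") genes$start[i] else genes$end[i] - 1
      dirn <- if (genes$strand[i] == "+") 1 else -1
      centers <- tssp + dirn * koff
      nk <- rpois(length(centers), depth * st$occupancy)
      pos <- rep(centers, nk)
      if (length(pos) && st$jitter > 0) pos <- round(pos + rnorm(length(pos), 0, st$jitter))
      pos <- pos[pos >= 0 & pos < cfg$chrom_sizes[[genes$chrom[i]]]]
      track <- add_reads(track, genes$chrom[i], pos, "+")
    }
    track
  })
}

#' Write a synthetic world to disk
#'
#' Writes `genes.bed` (BED6+biotype), `origins.bed`, `truth.tsv` and
#' `chrom.sizes` under `dir`.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gene_annotation(world$genes, file.path(dir, "genes.bed"))
  write_origin_annotation(world$origins, file.path(dir, "origins.bed"))
  data.table::fwrite(world$truth, file.path(dir, "truth.tsv"), sep = "\t")
  write_chrom_sizes(world$config$chrom_sizes, file.path(dir, "chrom.sizes"))
  invisible(dir)
}
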