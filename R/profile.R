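#' 5'/3' RNA Pol II ratio for one gene
#'
#' Reads from the TSS to `window` bp downstream are summed and divided by
#' the sum of reads from `window` bp upstream of the TTS to the TTS,
#' strand-aware (windows reflect on the minus strand). The figure-scale
#' default window is 300 bp; an alternative 250 bp convention also
#' appears in the field, so the window is a parameter. For genes shorter
#' than twice the window the two windows overlap within the gene body
#' (they are never extended beyond it); genes shorter than the window, or
#' with an empty 3' window, yield `NA` (undefined, excluded from strain
#' vectors).
#'
#' @param track a normalized [signal_track].
#' @param gene one-row [gene_set].
#' @param window window size in bp (default 300).
#' @return the ratio, or `NA_real_` when undefined.
#' @export
five_three_ratio <- function(track, gene, window = 300) {
  len <- gene$end - gene$start
  if (len < window) return(NA_real_)
  if (gene$strand == "+") {
    r5 <- sum(track_slice(track, gene$chrom, gene$start, gene$start + window, "+"))
    r3 <- sum(track_slice(track, gene$chrom, gene$end - window, gene$end, "+"))
  } else {
    r5 <- sum(track_slice(track, gene$chrom, gene$end - window, gene$end, "-"))
    r3 <- sum(track_slice(track, gene$chrom, gene$start, gene$start + window, "-"))
  }
  if (r3 <= 0) return(NA_real_)
  r5 / r3
}

#' Strain-level vector of 5'/3' ratios
#'
#' Genes shorter than `min_length` (default twice the window, so the TSS
#' and TTS windows cannot overlap) are excluded, as are genes with an
#' undefined ratio; exclusion counts are attached as attributes
#' `n_short` and `n_undefined`.
#'
#' @inheritParams five_three_ratio
#' @param genes a [gene_set].
#' @param min_length minimum gene length for eligibility.
#' @return named numeric vector of ratios for eligible genes.
#' @export
five_three_ratios <- function(track, genes, window = 300, min_length = 2 * window) {
  len <- genes$end - genes$start
  eligible <- len >= min_length
  ratios <- vapply(which(eligible), function(i) {
    five_three_ratio(track, genes[i, ], window)
  }, numeric(1))
  names(ratios) <- genes$id[eligible]
  out <- ratios[!is.na(ratios)]
  attr(out, "n_short") <- sum(!eligible)
  attr(out, "n_undefined") <- sum(is.na(ratios))
  out
}

rebin_mean <- function(v, bins) {
  idx <- floor((seq_along(v) - 1) * bins / length(v)) + 1L
  as.numeric(tapply(v, idx, mean))
}

#' Expression-normalized metagene profile
#'
#' Each gene's region from `flank_up` bp upstream of the TSS to
#' `flank_down` bp downstream of the TTS (strand-oriented) is fitted into
#' `bins` bins by averaging the source bases falling in each bin, then
#' divided by that gene's mean per-bp signal over its body (expression
#' normalization), so every gene contributes on the same scale. The
#' profile is the per-bin mean across genes with a 95% normal-theory
#' confidence band. Only genes with body length > `min_body` are used;
#' genes whose flanks cross a chromosome edge or whose body signal is
#' zero are excluded (counted in attributes).
#'
#' @param track a normalized [signal_track].
#' @param genes a [gene_set].
#' @param bins number of bins (default 500).
#' @param flank_up,flank_down flank sizes in bp (defaults 100 and 200).
#' @param min_body minimum gene body length in bp (default 500).
#' @return data.frame of class `metagene_profile`: bin, mean, lo, hi;
#'   attributes `n_genes`, `n_excluded_short`, `n_excluded_edge`,
#'   `n_excluded_zero`.
#' @export
metagene <- function(track, genes, bins = 500, flank_up = 100, flank_down = 200,
                     min_body = 500) {
  len <- genes$end - genes$start
  keep <- len > min_body
  n_short <- sum(!keep)
  mat <- matrix(NA_real_, nrow = 0, ncol = bins)
  n_edge <- 0L; n_zero <- 0L
  for (i in which(keep)) {
    g <- genes[i, ]
    size <- track$chrom_sizes[[g$chrom]]
    lo <- g$start - if (g$strand == "+") flank_up else flank_down
    hi <- g$end + if (g$strand == "+") flank_down else flank_up
    if (lo < 0 || hi > size) { n_edge <- n_edge + 1L; next }
    v <- track_slice(track, g$chrom, lo, hi, g$strand)
    if (g$strand == "-") v <- rev(v)
    body <- track_slice(track, g$chrom, g$start, g$end, g$strand)
    bm <- mean(body)
    if (bm <= 0) { n_zero <- n_zero + 1L; next }
    mat <- rbind(mat, rebin_mean(v, bins) / bm)
  }
  if (nrow(mat) == 0L) stop("no eligible genes for metagene profile")
  mu <- colMeans(mat)
  se <- apply(mat, 2, sd) / sqrt(nrow(mat))
  out <- data.frame(bin = seq_len(bins), mean = mu,
                    lo = mu - 1.96 * se, hi = mu + 1.96 * se)
  attr(out, "n_genes") <- nrow(mat)
  attr(out, "n_excluded_short") <- n_short
  attr(out, "n_excluded_edge") <- n_edge
  attr(out, "n_excluded_zero") <- n_zero
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' @rdname metagene
#' @param tracks named list of normalized tracks, one per strain.
#' @param ... passed on to [metagene()].
#' @export
metagene_profiles <- function(tracks, genes, ...) {
  lapply(tracks, metagene, genes = genes, ...)
}

#' Length-ordered log2 fold-change heatmap matrix
#'
#' For each gene, signal in `bin_size` bp bins over offsets 0..span-1
#' downstream of the TSS (strand-oriented) is compared between mutant and
#' wild type as `log2((mut + pc) / (WT + pc))`; bins past the gene's TTS
#' (or past the chromosome end) are masked `NA`. Rows are ordered by
#' increasing gene length.
#'
#' @param track_WT,track_mut normalized [signal_track]s on a common batch.
#' @param genes a [gene_set].
#' @param span bp downstream of the TSS (default 4000).
#' @param bin_size bin width in bp (default 25).
#' @param pseudocount added to both binned signals (default 1).
#' @return numeric matrix (genes x bins) with rownames = gene ids ordered
#'   by gene length; attribute `gene_length`.
#' @export
heatmap_matrix <- function(track_WT, track_mut, genes, span = 4000,
                           bin_size = 25, pseudocount = 1) {
  nb <- span %/% bin_size
  len <- genes$end - genes$start
  o <- order(len, method = "radix")
  genes <- genes[o, ]; len <- len[o]
  gene_bins <- function(track, g) {
    size <- track$chrom_sizes[[g$chrom]]
    span_g <- min(span, g$end - g$start)
    if (g$strand == "+") {
      span_g <- min(span_g, size - g$start)
      v <- track_slice(track, g$chrom, g$start, g$start + span_g, "+")
    } else {
      span_g <- min(span_g, g$end)
      v <- track_slice(track, g$chrom, g$end - span_g, g$end, "-")
      v <- rev(v)
    }
    idx <- ((seq_len(span_g) - 1) %/% bin_size) + 1L
    b <- rep(NA_real_, nb)
    m <- tapply(v, idx, mean)
    b[as.integer(names(m))] <- as.numeric(m)
    b
  }
  out <- t(vapply(seq_len(nrow(genes)), function(i) {
    wt <- gene_bins(track_WT, genes[i, ])
    mu <- gene_bins(track_mut, genes[i, ])
    log2((mu + pseudocount) / (wt + pseudocount))
  }, numeric(nb)))
  rownames(out) <- genes$id
  attr(out, "gene_length") <- setNames(len, genes$id)
  out
}
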