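#' Sum normalized signal over annotated regions
#'
#' Read counts per region are obtained by summing normalized per-base
#' signal over the region of interest. In `sense` mode the strand matching
#' each region is summed; in `antisense` mode the opposite strand over the
#' same gene body (used for cryptic antisense transcription). Overlapping
#' regions each receive the full signal of their own interval.
#'
#' @param track a normalized [signal_track].
#' @param regions a [gene_set].
#' @param mode `"sense"` or `"antisense"`.
#' @return data.frame of class `counts_table`: `region_id`, `class`,
#'   `count`.
#' @export
quantify_regions <- function(track, regions, mode = c("sense", "antisense")) {
  mode <- match.arg(mode)
  counts <- vapply(seq_len(nrow(regions)), function(i) {
    strand <- regions$strand[i]
    if (mode == "antisense") strand <- if (strand == "+") "-" else "+"
    sum(track_slice(track, regions$chrom[i], regions$start[i], regions$end[i], strand))
  }, numeric(1))
  out <- data.frame(region_id = regions$id,
                    class = if (mode == "antisense") "antisense" else regions$biotype,
                    count = counts, stringsAsFactors = FALSE)
  class(out) <- c("counts_table", "data.frame")
  out
}

#' Quantify a set of samples into one long counts table
#'
#' @param samples list of normalized [library_sample] objects.
#' @param regions a [gene_set].
#' @param mode passed to [quantify_regions()].
#' @return long data.frame: region_id, class, sample_id, genotype,
#'   timepoint, replicate, count.
#' @export
quantify_samples <- function(samples, regions, mode = c("sense", "antisense")) {
  mode <- match.arg(mode)
  out <- do.call(rbind, lapply(samples, function(s) {
    q <- quantify_regions(s$track, regions, mode)
    q$sample_id <- s$sample_id
    q$genotype <- s$genotype
    q$timepoint <- s$timepoint
    q$replicate <- s$replicate
    q
  }))
  rownames(out) <- NULL
  out
}

#' Fold changes between two conditions with BH-adjusted flags
#'
#' `log2FC = log2((mean_B + pc) / (mean_A + pc))`. When both conditions
#' have >= 2 replicates, p-values come from a two-sided Welch t-test on
#' `log2(count + pc)` across replicates (a deliberately simple,
#' transparent test standing in for negative-binomial machinery); with
#' fewer replicates p = 1 and flagging depends on the fold change alone.
#' q-values are Benjamini-Hochberg over all tested regions.
#'
#' @param counts_A,counts_B numeric matrices (regions x replicates) with
#'   identical rownames (region ids), or vectors for single replicates.
#' @param pseudocount added before logs and ratios (> 0, default 1).
#' @param fc_threshold,fdr_threshold thresholds used for the `flag_up` /
#'   `flag_down` columns (defaults 1.5 and 0.05).
#' @return data.frame of class `fold_change_table`: region_id, mean_A,
#'   mean_B, log2FC, p_value, q_value, flag_up, flag_down.
#' @export
fold_change_table <- function(counts_A, counts_B, pseudocount = 1,
                              fc_threshold = 1.5, fdr_threshold = 0.05) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  A <- as.matrix(counts_A); B <- as.matrix(counts_B)
  if (nrow(A) == 0L) stop("zero regions")
  if (nrow(A) != nrow(B)) stop("counts_A and counts_B must cover the same regions")
  ids <- rownames(A) %||% as.character(seq_len(nrow(A)))
  mean_A <- rowMeans(A); mean_B <- rowMeans(B)
  log2FC <- log2((mean_B + pseudocount) / (mean_A + pseudocount))
  p <- rep(1, nrow(A))
  if (ncol(A) >= 2L && ncol(B) >= 2L) {
    la <- log2(A + pseudocount); lb <- log2(B + pseudocount)
    p <- vapply(seq_len(nrow(A)), function(i) {
      x <- la[i, ]; y <- lb[i, ]
      if (sd(x) == 0 && sd(y) == 0) {
        return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
      }
      tryCatch(t.test(x, y)$p.value, error = function(e) 1)
    }, numeric(1))
  }
  q <- p.adjust(p, method = "BH")
  fc <- 2^log2FC
  out <- data.frame(region_id = ids, mean_A = mean_A, mean_B = mean_B,
                    log2FC = log2FC, p_value = p, q_value = q,
                    flag_up = fc >= fc_threshold & q <= fdr_threshold,
                    flag_down = fc <= 1 / fc_threshold & q <= fdr_threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("fold_change_table", "data.frame")
  out
}

#' Count regulated regions at the fixed fold-change / FDR thresholds
#'
#' @param table a [fold_change_table()].
#' @param fc_threshold fold-change threshold (default 1.5).
#' @param fdr_threshold FDR threshold on BH q-values (default 0.05).
#' @return named integer vector `c(n_up, n_down)`.
#' @export
count_regulated <- function(table, fc_threshold = 1.5, fdr_threshold = 0.05) {
  if (nrow(table) == 0L) return(c(n_up = 0L, n_down = 0L))
  fc <- 2^table$log2FC
  c(n_up = sum(fc >= fc_threshold & table$q_value <= fdr_threshold),
    n_down = sum(fc <= 1 / fc_threshold & table$q_value <= fdr_threshold))
}
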