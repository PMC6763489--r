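#' Centered moving average with reflected boundaries
#' @param x numeric vector.
#' @param width odd window width in bp; `width <= 1` returns `x`.
#' @return smoothed vector, same length.
#' @export
smooth_profile <- function(x, width = 31) {
  if (width <= 1) return(x)
  if (width %% 2 == 0) width <- width + 1
  h <- (width - 1) / 2
  xx <- c(rev(x[seq_len(h) + 1L]), x, rev(x[length(x) - seq_len(h)]))
  as.numeric(stats::filter(xx, rep(1 / width, width), sides = 2))[h + seq_along(x)]
}

#' TSS-aligned average nucleosome dyad profile
#'
#' Extracts the strand-oriented window `flank[1]..flank[2]` bp around
#' each gene's TSS from an (unstranded) dyad-density track and averages
#' across genes; genes whose window leaves the chromosome are skipped and
#' counted. Optional moving-average smoothing is recorded on the result.
#'
#' @param dyad_track a [signal_track] of dyad densities.
#' @param genes a [gene_set].
#' @param flank integer vector `c(upstream, downstream)` offsets relative
#'   to the TSS (default `c(-200, 1400)`).
#' @param smooth_width moving-average width in bp (0 = none).
#' @return data.frame of class `nucleosome_profile`: offset, density;
#'   attributes `n_genes`, `n_skipped`, `smooth_width`.
#' @export
tss_profile <- function(dyad_track, genes, flank = c(-200, 1400), smooth_width = 0) {
  offs <- flank[1]:flank[2]
  acc <- numeric(length(offs))
  n <- 0L; skipped <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tssp <- if (g$strand == "+") g$start else g$end - 1
    pos <- if (g$strand == "+") tssp + offs else tssp - offs
    if (min(pos) < 0 || max(pos) >= dyad_track$chrom_sizes[[g$chrom]]) {
      skipped <- skipped + 1L
      next
    }
    v <- dyad_track$plus[[g$chrom]][pos + 1L] + dyad_track$minus[[g$chrom]][pos + 1L]
    acc <- acc + v
    n <- n + 1L
  }
  if (n == 0L) stop("no genes with a complete TSS window")
  dens <- acc / n
  if (smooth_width > 1) dens <- smooth_profile(dens, smooth_width)
  out <- data.frame(offset = offs, density = dens)
  attr(out, "n_genes") <- n
  attr(out, "n_skipped") <- skipped
  attr(out, "smooth_width") <- smooth_width
  class(out) <- c("nucleosome_profile", "data.frame")
  out
}

local_extrema <- function(y) {
  d <- diff(y)
  s <- sign(d)
  nz <- s != 0
  run <- rle(s[nz])
  idx_nz <- which(nz)
  ends <- cumsum(run$lengths)
  peaks <- integer(0); troughs <- integer(0)
  if (length(run$values) >= 2L) {
    for (j in seq_len(length(run$values) - 1L)) {
      at <- idx_nz[ends[j]] + 1L   # index in y where the slope run ends
      if (run$values[j] > 0 && run$values[j + 1L] < 0) peaks <- c(peaks, at)
      if (run$values[j] < 0 && run$values[j + 1L] > 0) troughs <- c(troughs, at)
    }
  }
  list(peaks = peaks, troughs = troughs)
}

# Remove peaks whose prominence (height above the higher flanking trough)
# is below `thr`, merging segments so peaks and troughs stay alternating.
prune_extrema <- function(y, peaks, troughs, thr) {
  repeat {
    if (length(peaks) == 0L) break
    left <- vapply(peaks, function(p) {
      t <- troughs[troughs < p]
      if (length(t)) max(t) else which.min(y[seq_len(p)])
    }, numeric(1))
    right <- vapply(peaks, function(p) {
      t <- troughs[troughs > p]
      if (length(t)) min(t) else p - 1L + which.min(y[p:length(y)])
    }, numeric(1))
    prom <- y[peaks] - pmax(y[left], y[right])
    k <- which.min(prom)
    if (prom[k] >= thr) break
    tl <- troughs[troughs < peaks[k]]
    tr <- troughs[troughs > peaks[k]]
    if (length(tl) && length(tr)) {
      drop_t <- if (y[max(tl)] > y[min(tr)]) max(tl) else min(tr)
      troughs <- setdiff(troughs, drop_t)
    } else if (length(tl)) {
      troughs <- setdiff(troughs, max(tl))
    } else if (length(tr)) {
      troughs <- setdiff(troughs, min(tr))
    }
    peaks <- peaks[-k]
  }
  list(peaks = peaks, troughs = troughs)
}

#' Call positioned-nucleosome peaks on a TSS-aligned profile
#'
#' The profile is smoothed (moving average, recorded), local extrema are
#' found by sign changes of the discrete derivative, the
#' nucleosome-depleted region (NDR) is anchored at the global minimum
#' within `ndr_range`, and the first peak downstream of it is called +1.
#' The first `expected_peaks` peaks are retained with their flanking
#' troughs (the NDR minimum flanks +1 on the left; peaks and troughs
#' alternate by construction).
#'
#' @param profile a `nucleosome_profile` from [tss_profile()].
#' @param expected_peaks number of peaks to retain (default 7).
#' @param smooth_width smoothing applied before calling, unless the
#'   profile was already smoothed (default 31 bp).
#' @param ndr_range offsets searched for the NDR minimum
#'   (default `c(-150, 50)`).
#' @param min_prominence minimum peak prominence as a fraction of the
#'   profile's dynamic range; smaller wiggles are pruned (default 0.05).
#' @return list of class `peak_calls`: data.frame `peaks` (index, offset,
#'   height, trough_left_offset, trough_left, trough_right_offset,
#'   trough_right), `ndr_offset`, `smooth_width`.
#' @export
call_peaks <- function(profile, expected_peaks = 7, smooth_width = 31,
                       ndr_range = c(-150, 50), min_prominence = 0.05) {
  y <- profile$density
  if ((attr(profile, "smooth_width") %||% 0) <= 1 && smooth_width > 1) {
    y <- smooth_profile(y, smooth_width)
  }
  offs <- profile$offset
  no_peaks <- function(msg) {
    stop(errorCondition(paste0("NoPeaks: ", msg), class = c("noPeaks", "error")))
  }
  if (max(y) - min(y) <= .Machine$double.eps * max(abs(y), 1)) {
    no_peaks("profile is flat")
  }
  ex <- local_extrema(y)
  ex <- prune_extrema(y, ex$peaks, ex$troughs,
                      min_prominence * (max(y) - min(y)))
  in_ndr <- which(offs >= ndr_range[1] & offs <= ndr_range[2])
  if (length(in_ndr) == 0L) no_peaks("ndr_range outside profile")
  ndr_i <- in_ndr[which.min(y[in_ndr])]
  peaks <- ex$peaks[ex$peaks > ndr_i]
  if (length(peaks) < 4L) no_peaks(sprintf("only %d peaks detected", length(peaks)))
  peaks <- head(peaks, expected_peaks)
  trough_between <- function(a, b) {
    seg <- seq.int(a, b)
    seg[which.min(y[seg])]
  }
  tl <- integer(length(peaks)); trr <- integer(length(peaks))
  tl[1] <- ndr_i
  if (length(peaks) > 1L) {
    for (k in 2:length(peaks)) tl[k] <- trough_between(peaks[k - 1L], peaks[k])
  }
  trr[seq_len(length(peaks) - 1L)] <- tl[-1L]
  nxt <- ex$peaks[ex$peaks > peaks[length(peaks)]]
  last_seg_end <- if (length(nxt)) nxt[1] else length(y)
  trr[length(peaks)] <- trough_between(peaks[length(peaks)], last_seg_end)
  pk <- data.frame(index = seq_along(peaks), offset = offs[peaks], height = y[peaks],
                   trough_left_offset = offs[tl], trough_left = y[tl],
                   trough_right_offset = offs[trr], trough_right = y[trr])
  structure(list(peaks = pk, ndr_offset = offs[ndr_i],
                 smooth_width = max(smooth_width, attr(profile, "smooth_width") %||% 0)),
            class = "peak_calls")
}

#' Nucleosome maturation metrics from peak calls
#'
#' Peak/trough ratio: mean over nucleosomes +2..+7 (those present) of
#' peak height divided by the mean of its two flanking trough heights.
#' Linker length: mean over the pairs (+1,+2), (+2,+3), (+3,+4) of
#' peak-to-peak spacing minus the canonical 147 bp nucleosome footprint
#' (per-pair values are also reported; negative linkers are flagged).
#'
#' @param calls a `peak_calls` object.
#' @param footprint nucleosome footprint subtracted from spacings
#'   (default 147 bp).
#' @return list of class `maturation_metrics`: `peak_trough_ratio`,
#'   `linker_length`, `linkers` (named per-pair vector), `spacings`,
#'   `n_peaks`.
#' @export
maturation_metrics <- function(calls, footprint = 147) {
  pk <- calls$peaks
  if (nrow(pk) < 4L) stop("need at least 4 called peaks for maturation metrics")
  sel <- pk$index >= 2 & pk$index <= 7
  tr <- (pk$trough_left[sel] + pk$trough_right[sel]) / 2
  ok <- tr > 0
  ratio <- mean(pk$height[sel][ok] / tr[ok])
  pairs <- seq_len(min(3L, nrow(pk) - 1L))
  spacings <- pk$offset[pairs + 1L] - pk$offset[pairs]
  linkers <- spacings - footprint
  names(linkers) <- sprintf("+%d/+%d", pairs, pairs + 1L)
  if (any(linkers < 0)) {
    warning("negative linker length(s): ", paste(round(linkers[linkers < 0]), collapse = ", "))
  }
  structure(list(peak_trough_ratio = ratio, linker_length = mean(linkers),
                 linkers = linkers, spacings = spacings, n_peaks = nrow(pk)),
            class = "maturation_metrics")
}

#' Summarize maturation metrics across chase timepoints
#'
#' Mean and standard deviation of each metric across timepoints per
#' (genotype, chromatin state); with a single timepoint the SD is `NA`.
#'
#' @param metrics data.frame with columns genotype, state, timepoint,
#'   peak_trough_ratio, linker_length (one row per profile).
#' @return data.frame: genotype, state, n_timepoints, ratio_mean,
#'   ratio_sd, linker_mean, linker_sd.
#' @export
compare_states <- function(metrics) {
  dt <- data.table::as.data.table(metrics)
  out <- dt[, list(n_timepoints = .N,
                   ratio_mean = mean(peak_trough_ratio),
                   ratio_sd = if (.N > 1) sd(peak_trough_ratio) else NA_real_,
                   linker_mean = mean(linker_length),
                   linker_sd = if (.N > 1) sd(linker_length) else NA_real_),
            by = c("genotype", "state")]
  as.data.frame(out)
}
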