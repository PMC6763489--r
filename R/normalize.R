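#' Spike-in scale factor
#'
#' Libraries are normalized by scaling the uniquely mapped spike-in
#' (S. pombe) reads to a fixed target of 100,000: the factor is
#' `spike_target / spike_reads`.
#'
#' @param spike_reads uniquely mapped spike-in read count (> 0).
#' @param spike_target scaling target (default 100,000 reads).
#' @return the spike scale factor.
#' @export
compute_spike_factor <- function(spike_reads, spike_target = 1e5) {
  assert_scalar_number(spike_target, "spike_target", positive = TRUE)
  if (!is.numeric(spike_reads) || length(spike_reads) != 1L ||
      !is.finite(spike_reads) || spike_reads <= 0) {
    stop("spike_reads must be a single count > 0; sample is not normalizable")
  }
  spike_target / spike_reads
}

#' Batch depth factor from reference-genotype libraries
#'
#' After spike scaling, the spike-scaled read counts of the reference
#' (wild-type) libraries in a sequencing batch are scaled to 1 M reads;
#' the same factor is applied to every sample in the batch. With several
#' reference replicates the factor uses their mean spike-scaled count.
#'
#' @param batch list of [library_sample] objects forming one batch.
#' @param reference_genotype genotype whose libraries define the batch
#'   depth (default `"WT"`).
#' @param depth_target scaling target (default 1e6 reads).
#' @param spike_target passed to [compute_spike_factor()].
#' @return the shared depth factor.
#' @export
compute_depth_factor <- function(batch, reference_genotype = "WT",
                                 depth_target = 1e6, spike_target = 1e5) {
  ref <- Filter(function(s) s$genotype == reference_genotype, batch)
  if (length(ref) == 0L) {
    stop("no sample of reference genotype '", reference_genotype, "' in batch")
  }
  scaled <- vapply(ref, function(s) {
    compute_spike_factor(s$spike_reads, spike_target) * s$target_reads
  }, numeric(1))
  depth_target / mean(scaled)
}

#' Apply the composite spike x depth normalization to a sample
#'
#' Multiplies every track value by `spike_factor * depth_factor`, records
#' both factors in the track's normalization log, and stores them on the
#' sample. Re-normalizing an already normalized sample is an error.
#'
#' @param sample a [library_sample].
#' @param depth_factor batch depth factor from [compute_depth_factor()].
#' @param spike_target passed to [compute_spike_factor()].
#' @return the normalized sample.
#' @export
apply_normalization <- function(sample, depth_factor, spike_target = 1e5) {
  if (nrow(sample$track$normalization) > 0L) {
    stop("sample '", sample$sample_id, "' is already normalized")
  }
  assert_scalar_number(depth_factor, "depth_factor", positive = TRUE)
  sf <- compute_spike_factor(sample$spike_reads, spike_target)
  sample$track <- scale_track(sample$track, sf, "spike_factor")
  sample$track <- scale_track(sample$track, depth_factor, "depth_factor")
  sample$spike_factor <- sf
  sample$depth_factor <- depth_factor
  sample
}

#' Normalize every sample in a batch
#'
#' Computes per-sample spike factors and the shared reference depth
#' factor, applies both to every sample, and returns the samples together
#' with an auditable factor table.
#'
#' @inheritParams compute_depth_factor
#' @return list with `samples` (normalized list) and `factors`
#'   (data.frame: sample_id, genotype, timepoint, replicate, spike_reads,
#'   target_reads, spike_factor, depth_factor, composite).
#' @export
normalize_batch <- function(batch, reference_genotype = "WT",
                            depth_target = 1e6, spike_target = 1e5) {
  df <- compute_depth_factor(batch, reference_genotype, depth_target, spike_target)
  samples <- lapply(batch, apply_normalization, depth_factor = df,
                    spike_target = spike_target)
  names(samples) <- vapply(samples, `[[`, character(1), "sample_id")
  factors <- do.call(rbind, lapply(samples, function(s) {
    data.frame(sample_id = s$sample_id, genotype = s$genotype,
               timepoint = s$timepoint, replicate = s$replicate,
               spike_reads = s$spike_reads, target_reads = s$target_reads,
               spike_factor = s$spike_factor, depth_factor = s$depth_factor,
               composite = s$spike_factor * s$depth_factor)
  }))
  rownames(factors) <- NULL
  list(samples = samples, factors = factors)
}
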