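#' Sequencing library samples
#'
#' A `library_sample` bundles one sequencing library: its signal track, the
#' spike-in read count used for normalization, the total target-genome read
#' count, and the design labels (genotype, cell-cycle timepoint, replicate).
#'
#' @param sample_id unique sample identifier.
#' @param genotype strain / condition label (e.g. `"WT"`).
#' @param timepoint one of `"G1"`, `"S30"`, `"S60"`, `"S90"`, `"async"`.
#' @param replicate replicate number, >= 1.
#' @param track a [signal_track] of 3'-end counts.
#' @param spike_reads uniquely mapped spike-in reads (> 0).
#' @param target_reads uniquely mapped target-genome reads.
#' @return an object of class `library_sample`.
#' @export
library_sample <- function(sample_id, genotype, timepoint, replicate,
                           track, spike_reads, target_reads) {
  if (!timepoint %in% c("G1", "S30", "S60", "S90", "async")) {
    stop("unknown timepoint: ", timepoint)
  }
  if (replicate < 1) stop("replicate must be >= 1")
  if (spike_reads <= 0) stop("spike_reads must be > 0 for a normalizable sample")
  structure(list(sample_id = sample_id, genotype = genotype,
                 timepoint = timepoint, replicate = as.integer(replicate),
                 track = track, spike_reads = as.numeric(spike_reads),
                 target_reads = as.numeric(target_reads),
                 spike_factor = NA_real_, depth_factor = NA_real_),
            class = "library_sample")
}

#' @export
print.library_sample <- function(x, ...) {
  cat(sprintf("library_sample %s: %s %s rep%d, %g target / %g spike reads\n",
              x$sample_id, x$genotype, x$timepoint, x$replicate,
              x$target_reads, x$spike_reads))
  invisible(x)
}

#' Read / write a sample sheet
#'
#' TSV with header columns `sample_id`, `genotype`, `timepoint`,
#' `replicate`, `spike_reads`, `target_reads`, `track_plus`, `track_minus`
#' (track paths relative to the sheet's directory).
#'
#' @param path sheet path.
#' @return data.frame (read) or path invisibly (write).
#' @export
read_sample_sheet <- function(path) {
  sheet <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("sample_id", "genotype", "timepoint", "replicate",
            "spike_reads", "target_reads", "track_plus", "track_minus")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  sheet
}

#' @rdname read_sample_sheet
#' @param sheet sample-sheet data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  data.table::fwrite(sheet, path, sep = "\t")
  invisible(path)
}

#' Load every sample on a sheet into `library_sample` objects
#' @param sheet data.frame from [read_sample_sheet()].
#' @param chrom_sizes named chromosome lengths.
#' @param dir directory track paths are relative to.
#' @return named list of [library_sample] objects.
#' @export
load_samples <- function(sheet, chrom_sizes, dir = ".") {
  out <- lapply(seq_len(nrow(sheet)), function(i) {
    r <- sheet[i, ]
    tr <- read_signal_track(file.path(dir, r$track_plus),
                            file.path(dir, r$track_minus), chrom_sizes)
    library_sample(r$sample_id, r$genotype, r$timepoint, r$replicate,
                   tr, r$spike_reads, r$target_reads)
  })
  names(out) <- sheet$sample_id
  out
}
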