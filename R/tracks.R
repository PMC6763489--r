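#' Strand-specific per-base signal tracks
#'
#' A `signal_track` holds dense non-negative per-base arrays at 1 bp
#' resolution, one array per strand per chromosome, plus a normalization
#' log recording every scale factor applied (name, value) in order. The
#' same container carries NET-seq 3'-end counts (stranded) and nucleosome
#' dyad densities (unstranded: all mass conventionally on the plus arrays).
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param plus,minus named lists of numeric vectors (one per chromosome);
#'   missing chromosomes are filled with zeros.
#' @return an object of class `signal_track`.
#' @export
signal_track <- function(chrom_sizes, plus = NULL, minus = NULL) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stop("'chrom_sizes' must be a named vector")
  }
  mk <- function(src) {
    out <- lapply(names(chrom_sizes), function(ch) {
      v <- src[[ch]]
      if (is.null(v)) return(numeric(chrom_sizes[[ch]]))
      if (length(v) != chrom_sizes[[ch]]) {
        stop(sprintf("array length %d != chromosome length %d for %s",
                     length(v), chrom_sizes[[ch]], ch))
      }
      if (any(v < 0)) stop("signal values must be >= 0")
      as.numeric(v)
    })
    names(out) <- names(chrom_sizes)
    out
  }
  structure(list(plus = mk(plus), minus = mk(minus),
                 chrom_sizes = chrom_sizes,
                 normalization = data.frame(factor_name = character(),
                                            factor_value = numeric())),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d chromosome(s), total signal %.4g (+) / %.4g (-)\n",
              length(x$chrom_sizes), track_total(x, "+"), track_total(x, "-")))
  if (nrow(x$normalization)) {
    cat("normalization:", paste(sprintf("%s=%.6g", x$normalization$factor_name,
                                        x$normalization$factor_value), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Total signal in a track
#'
#' @param track a [signal_track].
#' @param strand `"+"`, `"-"`, or `"both"`.
#' @return numeric total.
#' @export
track_total <- function(track, strand = "both") {
  p <- sum(vapply(track$plus, sum, numeric(1)))
  m <- sum(vapply(track$minus, sum, numeric(1)))
  switch(strand, "+" = p, "-" = m, both = p + m)
}

#' Multiply every track value by a scalar, recording the factor
#' @param track a [signal_track].
#' @param factor positive scalar.
#' @param name label recorded in the normalization log.
#' @return the scaled track.
#' @export
scale_track <- function(track, factor, name = "scale") {
  assert_scalar_number(factor, "factor", positive = TRUE)
  track$plus <- lapply(track$plus, `*`, factor)
  track$minus <- lapply(track$minus, `*`, factor)
  track$normalization <- rbind(track$normalization,
                               data.frame(factor_name = name, factor_value = factor))
  track
}

#' Read a two-column chrom.sizes file
#' @param path TSV with columns chromosome name and length.
#' @return named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  cs <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "size"))
  if (any(cs$size <= 0)) stop("chromosome sizes must be > 0")
  setNames(as.numeric(cs$size), cs$chrom)
}

#' @rdname read_chrom_sizes
#' @param chrom_sizes named numeric vector to write.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  ch <- sort_chroms(names(chrom_sizes))
  writeLines(sprintf("%s\t%d", ch, as.integer(chrom_sizes[ch])), path)
  invisible(path)
}

read_bedgraph_into <- function(path, arrays, chrom_sizes) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(arrays)
  fields <- strsplit(lines[idx], "[ \t]+")
  n <- lengths(fields)
  if (any(n < 4L)) stop_parse(path, idx[which(n < 4L)[1]], "expected 4 bedGraph fields")
  chrom <- vapply(fields, `[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3)))
  value <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 4)))
  bad <- which(is.na(start) | is.na(end) | is.na(value))
  if (length(bad)) stop_parse(path, idx[bad[1]], "non-numeric field")
  bad <- which(!(chrom %in% names(chrom_sizes)))
  if (length(bad)) stop_parse(path, idx[bad[1]], paste0("unknown chromosome '", chrom[bad[1]], "'"))
  bad <- which(start < 0 | start >= end | end > chrom_sizes[chrom])
  if (length(bad)) stop_parse(path, idx[bad[1]], "interval outside chromosome bounds")
  bad <- which(value < 0)
  if (length(bad)) stop_parse(path, idx[bad[1]], "negative signal value")
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    pos <- sequence(end[sel] - start[sel], from = start[sel] + 1)
    arrays[[ch]][pos] <- rep(value[sel], end[sel] - start[sel])
  }
  arrays
}

#' Read a strand-specific signal track from a pair of bedGraph files
#'
#' Intervals are expanded to dense per-base arrays; uncovered bases are 0.
#' Intervals beyond the chromosome end or with negative values are errors.
#'
#' @param path_plus,path_minus bedGraph files for the two strands; pass
#'   `NULL` for `path_minus` to read an unstranded (dyad) track.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @return a [signal_track].
#' @export
read_signal_track <- function(path_plus, path_minus, chrom_sizes) {
  tr <- signal_track(chrom_sizes)
  tr$plus <- read_bedgraph_into(path_plus, tr$plus, chrom_sizes)
  if (!is.null(path_minus)) {
    tr$minus <- read_bedgraph_into(path_minus, tr$minus, chrom_sizes)
  }
  tr
}

write_bedgraph_file <- function(arrays, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in sort_chroms(names(arrays))) {
    v <- arrays[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    nz <- r$values != 0
    if (any(nz)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", ch, as.integer(starts[nz]),
                         as.integer(ends[nz]), sprintf("%.10g", r$values[nz])), con)
    }
  }
  invisible(path)
}

#' Write a signal track as run-length-merged bedGraph
#'
#' Zero runs are omitted; output order is chromosome (lexicographic, C
#' locale), then start, so identical tracks produce byte-identical files.
#'
#' @param track a [signal_track].
#' @param out_plus,out_minus output paths; `out_minus = NULL` writes the
#'   plus arrays only (unstranded track).
#' @export
write_signal_track <- function(track, out_plus, out_minus = NULL) {
  write_bedgraph_file(track$plus, out_plus)
  if (!is.null(out_minus)) write_bedgraph_file(track$minus, out_minus)
  invisible(track)
}

#' Extract per-base values over an interval
#' @param track a [signal_track].
#' @param chrom chromosome.
#' @param start,end 0-based half-open bounds.
#' @param strand `"+"`, `"-"`, or `"both"` (sum of strands).
#' @return numeric vector of length `end - start`.
#' @export
track_slice <- function(track, chrom, start, end, strand = "+") {
  if (!chrom %in% names(track$chrom_sizes)) stop("unknown chromosome: ", chrom)
  if (start < 0 || end > track$chrom_sizes[[chrom]] || start >= end) {
    stop(sprintf("interval [%s, %s) outside chromosome %s", start, end, chrom))
  }
  i <- (start + 1):end
  switch(strand,
         "+" = track$plus[[chrom]][i],
         "-" = track$minus[[chrom]][i],
         both = track$plus[[chrom]][i] + track$minus[[chrom]][i])
}

add_reads <- function(track, chrom, positions, strand) {
  if (length(positions) == 0L) return(track)
  tab <- tabulate(positions + 1L, nbins = track$chrom_sizes[[chrom]])
  if (strand == "+") {
    track$plus[[chrom]] <- track$plus[[chrom]] + tab
  } else {
    track$minus[[chrom]] <- track$minus[[chrom]] + tab
  }
  track
}
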