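#' Replication origins with firing-time labels
#'
#' Origins are points (0-based positions) labelled `early` or `late`.
#' The on-disk format is BED-like: chrom, start, end, name, timing; the
#' origin position is the interval start.
#'
#' @param chrom chromosome names.
#' @param position 0-based positions.
#' @param timing `"early"` or `"late"`.
#' @param name optional origin names.
#' @return a data.frame of class `origin_set`, sorted by (chrom, position).
#' @export
origin_set <- function(chrom, position, timing, name = NULL) {
  o <- data.frame(chrom = as.character(chrom), position = as.numeric(position),
                  timing = as.character(timing),
                  name = if (is.null(name)) sprintf("ARS%03d", seq_along(chrom)) else as.character(name),
                  stringsAsFactors = FALSE)
  bad <- setdiff(o$timing, c("early", "late"))
  if (length(bad)) stop("unknown origin timing label: ", paste(bad, collapse = ", "))
  if (any(o$position < 0)) stop("origin positions must be >= 0")
  o <- o[order(match(o$chrom, sort_chroms(o$chrom)), o$position, method = "radix"), ]
  rownames(o) <- NULL
  class(o) <- c("origin_set", "data.frame")
  o
}

#' Read / write origin annotations
#'
#' @param path BED-like file: chrom, start, end, name, timing; a timing
#'   label other than `early`/`late` is an error.
#' @return an `origin_set` (read) or the path invisibly (write).
#' @export
read_origin_annotation <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(origin_set(character(), numeric(), character()))
  fields <- strsplit(lines[idx], "[ \t]+")
  n <- lengths(fields)
  if (any(n < 5L)) stop_parse(path, idx[which(n < 5L)[1]], "expected 5 fields (chrom start end name timing)")
  timing <- vapply(fields, `[`, character(1), 5)
  bad <- which(!timing %in% c("early", "late"))
  if (length(bad)) {
    stop_parse(path, idx[bad[1]], paste0("unknown timing label '", timing[bad[1]], "'"))
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2)))
  badc <- which(is.na(start))
  if (length(badc)) stop_parse(path, idx[badc[1]], "non-numeric coordinate")
  origin_set(vapply(fields, `[`, character(1), 1), start, timing,
             vapply(fields, `[`, character(1), 4))
}

#' @rdname read_origin_annotation
#' @param origins an `origin_set`.
#' @export
write_origin_annotation <- function(origins, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s", origins$chrom,
                     as.integer(origins$position), as.integer(origins$position + 1),
                     origins$name, origins$timing), path)
  invisible(path)
}
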