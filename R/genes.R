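#' Gene sets
#'
#' A `gene_set` is a data.frame of transcribed regions with one row per
#' feature and columns `id`, `chrom`, `start`, `end`, `strand`, `biotype`.
#' Coordinates are 0-based half-open throughout the package (BED-native);
#' GFF3 input is converted on read. The transcription start site (TSS) of a
#' plus-strand gene is `start`; of a minus-strand gene `end - 1`. The
#' termination site (TTS) is symmetric.
#'
#' @param id character vector of unique feature identifiers.
#' @param chrom chromosome names.
#' @param start,end 0-based half-open interval bounds, `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @param biotype one of `"coding"`, `"CUT"`, `"SUT"`.
#' @return a data.frame of class `gene_set`.
#' @export
gene_set <- function(id, chrom, start, end, strand, biotype = "coding") {
  g <- data.frame(
    id = as.character(id), chrom = as.character(chrom),
    start = as.numeric(start), end = as.numeric(end),
    strand = as.character(strand),
    biotype = rep_len(as.character(biotype), length(id)),
    stringsAsFactors = FALSE
  )
  validate_gene_set(g)
  class(g) <- c("gene_set", "data.frame")
  g
}

validate_gene_set <- function(g) {
  if (nrow(g) == 0L) return(invisible(g))
  if (anyDuplicated(g$id)) {
    stop("duplicate gene ids: ", paste(unique(g$id[duplicated(g$id)]), collapse = ", "))
  }
  if (any(!g$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(g$start < 0) || any(g$start >= g$end)) {
    stop("gene coordinates must satisfy 0 <= start < end")
  }
  bad <- setdiff(g$biotype, c("coding", "CUT", "SUT"))
  if (length(bad)) stop("unknown biotype: ", paste(bad, collapse = ", "))
  invisible(g)
}

#' Transcription start / termination sites
#'
#' 0-based positions; strand-aware (`start` on plus, `end - 1` on minus for
#' the TSS, and symmetrically for the TTS).
#'
#' @param genes a [gene_set].
#' @return numeric vector of positions, one per gene.
#' @export
tss <- function(genes) ifelse(genes$strand == "+", genes$start, genes$end - 1)

#' @rdname tss
#' @export
tts <- function(genes) ifelse(genes$strand == "+", genes$end - 1, genes$start)

#' Read a gene annotation
#'
#' BED6 files are read as-is (0-based half-open); an optional seventh column
#' carries the biotype (`coding`/`CUT`/`SUT`, default `coding`). GFF3 files
#' (1-based closed) are imported through `rtracklayer` and converted to the
#' internal 0-based half-open convention; the `ID` (or `Name`) attribute
#' becomes the gene id and a `biotype` attribute is honoured when present.
#'
#' @param path file path.
#' @param format `"BED6"` or `"GFF3"`.
#' @return a [gene_set].
#' @export
read_gene_annotation <- function(path, format = c("BED6", "GFF3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "GFF3") {
    gr <- rtracklayer::import(path, format = "gff3")
    mc <- as.data.frame(gr)
    ids <- mc$ID %||% mc$Name
    if (is.null(ids) || any(is.na(ids))) stop("GFF3 features must carry an ID or Name attribute")
    biotype <- if (!is.null(mc$biotype)) ifelse(is.na(mc$biotype), "coding", mc$biotype) else "coding"
    strand <- as.character(mc$strand)
    if (any(!strand %in% c("+", "-"))) stop("unknown strand in GFF3 (must be + or -)")
    return(gene_set(ids, mc$seqnames, mc$start - 1, mc$end, strand, biotype))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(gene_set(character(), character(), numeric(), numeric(), character()))
  }
  fields <- strsplit(lines, "[ \t]+")
  n <- lengths(fields)
  bad <- which(n < 6L)
  if (length(bad)) stop_parse(path, bad[1], "expected at least 6 BED fields")
  get <- function(i) vapply(fields, `[`, character(1), i)
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  badc <- which(is.na(start) | is.na(end))
  if (length(badc)) stop_parse(path, badc[1], "non-numeric coordinate")
  strand <- get(6)
  bads <- which(!strand %in% c("+", "-"))
  if (length(bads)) stop_parse(path, bads[1], paste0("unknown strand '", strand[bads[1]], "'"))
  biotype <- vapply(fields, function(f) if (length(f) >= 7L) f[7] else "coding", character(1))
  gene_set(get(4), get(1), start, end, strand, biotype)
}

#' Write a gene annotation as BED6 (+ biotype column)
#'
#' Emits standard BED6 with the biotype as a seventh column, which
#' [read_gene_annotation()] accepts, so write/read round-trips are lossless.
#'
#' @param genes a [gene_set].
#' @param path output path.
#' @export
write_gene_annotation <- function(genes, path) {
  validate_gene_set(genes)
  if (nrow(genes) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  o <- order(match(genes$chrom, sort_chroms(genes$chrom)), genes$start, method = "radix")
  g <- genes[o, ]
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s\t%s",
                     g$chrom, as.integer(g$start), as.integer(g$end),
                     g$id, g$strand, g$biotype), path)
  invisible(path)
}
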