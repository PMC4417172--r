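# Plain-text interchange: BEDPE-like 10-column TSV for paired-end
# molecules, BED6 for whole molecules and gene models, headered TSV for
# lanes, decay series, calibration series and gene tables.

bedpe_cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                "name", "score", "strand1", "strand2")

#' Write scRNA reads as BEDPE
#'
#' One row per read: mate 1 is the single base of the capped 5' end, mate 2
#' the single base of the 3' end (0-based half-open), `name` the gene id,
#' both strand columns the read's strand.
#'
#' @param reads An `scrna_reads` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scrna_bedpe <- function(reads, path) {
  out <- data.frame(
    chrom1 = reads$chrom, start1 = reads$five_prime,
    end1 = reads$five_prime + 1L,
    chrom2 = reads$chrom, start2 = reads$three_prime,
    end2 = reads$three_prime + 1L,
    name = if (is.null(reads$gene_id)) "." else reads$gene_id,
    score = if (is.null(reads$sense)) 0L else as.integer(reads$sense),
    strand1 = reads$strand, strand2 = reads$strand
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read scRNA reads from BEDPE
#'
#' Inverse of [write_scrna_bedpe()]: mate 1 start is the 5' end, mate 2
#' start the 3' end. Strand columns are required.
#'
#' @param path BEDPE file (10 tab-separated columns, no header).
#' @return An `scrna_reads` data frame.
#' @export
read_scrna_bedpe <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 10L) stop("expected 10 BEDPE columns", call. = FALSE)
  names(x)[1:10] <- bedpe_cols
  if (!all(x$strand1 %in% c("+", "-"))) {
    stop("BEDPE strand columns are required ('+'/'-')", call. = FALSE)
  }
  reads <- data.frame(
    gene_id = as.character(x$name), chrom = x$chrom1, strand = x$strand1,
    five_prime = as.integer(x$start1), three_prime = as.integer(x$start2),
    sense = x$score == 1L, stringsAsFactors = FALSE
  )
  class(reads) <- c("scrna_reads", "data.frame")
  reads
}

#' Write ChIP fragments as BEDPE
#'
#' Mate 1 is the first base of the fragment, mate 2 its last base; `name`
#' carries the gene id when present. Strands are recorded as `"."`-free
#' `"+"` placeholders since fragment orientation is not used downstream.
#'
#' @param fragments A `chip_fragments` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chip_bedpe <- function(fragments, path) {
  out <- data.frame(
    chrom1 = fragments$chrom, start1 = fragments$start,
    end1 = fragments$start + 1L,
    chrom2 = fragments$chrom, start2 = fragments$end - 1L,
    end2 = fragments$end,
    name = if (is.null(fragments$gene_id)) "." else fragments$gene_id,
    score = 0L, strand1 = "+", strand2 = "+"
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read ChIP fragments from BEDPE
#'
#' The fragment interval is reconstructed as `[start1, end2)` and the
#' center derived as `floor((start + end) / 2)`.
#'
#' @param path BEDPE file path.
#' @return A `chip_fragments` data frame.
#' @export
read_chip_bedpe <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 10L) stop("expected 10 BEDPE columns", call. = FALSE)
  names(x)[1:10] <- bedpe_cols
  start <- as.integer(x$start1)
  end <- as.integer(x$end2)
  if (any(end <= start)) stop("fragment end must exceed start", call. = FALSE)
  frags <- data.frame(
    gene_id = as.character(x$name), chrom = x$chrom1,
    start = start, end = end, center = (start + end) %/% 2L,
    stringsAsFactors = FALSE
  )
  class(frags) <- c("chip_fragments", "data.frame")
  frags
}

#' Write whole molecules as BED6
#'
#' Writes scRNA reads or ChIP fragments as whole-molecule BED6 intervals
#' (0-based half-open), with the gene id as name.
#'
#' @param x An `scrna_reads` or `chip_fragments` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_molecules_bed <- function(x, path) {
  if (!is.null(x$five_prime)) {
    start <- pmin(x$five_prime, x$three_prime)
    end <- pmax(x$five_prime, x$three_prime) + 1L
    strand <- x$strand
  } else {
    start <- x$start
    end <- x$end
    strand <- "+"
  }
  out <- data.frame(
    chrom = x$chrom, start = start, end = end,
    name = if (is.null(x$gene_id)) "." else x$gene_id,
    score = 0L, strand = strand
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write and read gene models
#'
#' `write_gene_bed()` stores each gene as a BED6 line anchored on the
#' annotated TSS (a 1-bp interval), with the true TSS kept in an extra 7th
#' column so simulated annotation offsets survive a round trip;
#' `read_gene_bed()` reconstructs the [gene_models()] table (a missing 7th
#' column means true = annotated).
#'
#' @param genes A [gene_models()] data frame.
#' @param path File path.
#' @return `write_gene_bed()` returns `path` invisibly; `read_gene_bed()`
#'   a `gene_models` data frame.
#' @export
write_gene_bed <- function(genes, path) {
  genes <- as_gene_models(genes)
  out <- data.frame(
    chrom = genes$chrom, start = genes$annotated_tss,
    end = genes$annotated_tss + 1L, name = genes$gene_id,
    score = 0L, strand = genes$strand, true_tss = genes$true_tss
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_bed
#' @export
read_gene_bed <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 6L) stop("expected at least 6 BED columns", call. = FALSE)
  gene_models(
    gene_id = as.character(x[[4]]), chrom = x[[1]], strand = x[[6]],
    annotated_tss = as.integer(x[[2]]),
    true_tss = if (ncol(x) >= 7L) as.integer(x[[7]]) else as.integer(x[[2]])
  )
}

#' Headered TSV helpers for tabular inputs
#'
#' Thin wrappers writing/reading the pipeline's tabular formats: lane
#' profiles (`offset`, `intensity`, `is_thymine`), decay series (`time`,
#' `replicate`, `value`), calibration series (`fraction`, `signal`) and
#' gene tables (`gene_id`, `score`). Readers restore the pausekit classes.
#'
#' @param x The object to write.
#' @param path File path.
#' @return Writers return `path` invisibly; readers the restored object.
#' @name tsv_io
NULL

#' @rdname tsv_io
#' @export
write_lane_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname tsv_io
#' @export
read_lane_tsv <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  lane_profile(x$offset, x$intensity, x$is_thymine)
}

#' @rdname tsv_io
#' @export
write_decay_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname tsv_io
#' @param normalized Whether the stored series was normalized.
#' @export
read_decay_tsv <- function(path, normalized = FALSE) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  decay_series(x$time, x$replicate, x$value, normalized = normalized)
}

#' @rdname tsv_io
#' @export
write_table_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tsv_io
#' @export
read_table_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
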