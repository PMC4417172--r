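# Paired-end ChIP fragment-center analysis: promoter enrichment, the
# top-fraction gene filter, binned metagenes and promoter peak detection.

#' Promoter Pol II enrichment score
#'
#' Ratio of fragment-center density (centers per kb) in the promoter window
#' to the genome-wide background density. Counting is strand-agnostic and
#' uses fragment centers, matching the paired-end center logic of the rest
#' of the pipeline. The promoter interval is the half-open
#' `[tss - promoter_window, tss + promoter_window)`, i.e. 1 kb at the
#' default +/-500 nt window.
#'
#' @param fragments A `chip_fragments` data frame (needs `chrom`, `center`).
#' @param gene A single-row [gene_models()] entry; its annotated TSS anchors
#'   the promoter.
#' @param promoter_window Promoter half-width in nt (> 0).
#' @param genome_length Total genome length in bp used for the background
#'   density (> 0).
#' @return A single nonnegative enrichment score; 1 means promoter density
#'   equals background.
#' @examples
#' g <- gene_models("g1", "chr1", "+", 5000)
#' f <- data.frame(chrom = "chr1", center = seq(4500, 5499))
#' promoter_enrichment(f, g, genome_length = 10000)  # all centers in a 1 kb
#'                                                   # promoter of a 10 kb genome: 10
#' @export
promoter_enrichment <- function(fragments, gene, promoter_window = 500,
                                genome_length) {
  stopifnot_scalar_number(promoter_window, "promoter_window", positive = TRUE)
  stopifnot_scalar_number(genome_length, "genome_length", positive = TRUE)
  gene <- as_gene_models(gene)
  if (nrow(gene) != 1L) stop("`gene` must be a single gene model", call. = FALSE)
  n_total <- nrow(fragments)
  if (is.null(n_total) || n_total == 0L) {
    stop("zero background fragments: enrichment is undefined", call. = FALSE)
  }
  tss <- gene$annotated_tss
  in_prom <- fragments$chrom == gene$chrom &
    fragments$center >= tss - promoter_window &
    fragments$center < tss + promoter_window
  prom_len <- 2 * promoter_window
  (sum(in_prom) / prom_len) / (n_total / genome_length)
}

#' Retain the top-scoring fraction of genes
#'
#' Keeps the `ceiling(fraction * n)` genes with the highest scores (default
#' fraction 0.30, the top-30% promoter-enrichment filter applied before all
#' metagene analyses). Ties at the cut are broken by lexicographic
#' `gene_id`, making the selection deterministic and invariant to input row
#' order.
#'
#' @param gene_scores Data frame with columns `gene_id` (unique) and
#'   `score` (finite).
#' @param fraction Fraction of genes to retain, in (0, 1\].
#' @return The retained rows of `gene_scores`, ordered by decreasing score
#'   (ties by `gene_id`).
#' @examples
#' tab <- data.frame(gene_id = letters[1:10], score = 1:10)
#' select_top_fraction(tab, 0.3)$gene_id  # "j" "i" "h"
#' @export
select_top_fraction <- function(gene_scores, fraction = 0.30) {
  if (!is.data.frame(gene_scores) ||
      !all(c("gene_id", "score") %in% names(gene_scores))) {
    stop("`gene_scores` needs columns gene_id and score", call. = FALSE)
  }
  if (nrow(gene_scores) == 0L) stop("`gene_scores` is empty", call. = FALSE)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  }
  if (any(!is.finite(gene_scores$score))) {
    stop("scores must be finite", call. = FALSE)
  }
  if (anyDuplicated(gene_scores$gene_id)) {
    stop("gene_id values must be unique", call. = FALSE)
  }
  k <- as.integer(ceiling(fraction * nrow(gene_scores)))
  ord <- order(-gene_scores$score, gene_scores$gene_id)
  out <- gene_scores[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binned metagene profile around per-gene anchors
#'
#' Bins positions (ChIP fragment centers or scRNA ends) into fixed-width
#' TSS-relative bins around each gene's anchor and averages the per-gene
#' binned counts across genes. Minus-strand genes are mirrored before
#' binning so that positive offsets always mean downstream. Offsets cover
#' the half-open window `[-window, window)`; a position near two anchors
#' contributes to both. Total signal is conserved:
#' `sum(values) * n_genes` equals the number of in-window position/anchor
#' pairs.
#'
#' @param positions Data frame with columns `chrom` and `pos` (see
#'   [fragment_centers()] and [scrna_end_positions()]), or a bare numeric
#'   vector (assumed to share the chromosome of all anchors).
#' @param anchors A [gene_models()]-like data frame; the `anchor` column is
#'   used if present, otherwise `annotated_tss`.
#' @param window Half-width in nt; must be a positive multiple of
#'   `bin_size`.
#' @param bin_size Bin width in nt (> 0); 25 bp is the convention for ChIP
#'   centers, 1 bp for scRNA ends.
#' @return An object of class `metagene_profile`: a list with `bin_left`,
#'   `bin_right` (half-open bin edges), `bin_center`, `values` (mean count
#'   per gene per bin), `n_genes`, `bin_size`, `n_items` (in-window
#'   position/anchor pairs).
#' @examples
#' g <- gene_models("g1", "chr1", "+", 1000)
#' mp <- metagene(data.frame(chrom = "chr1", pos = 1000), g,
#'                window = 500, bin_size = 25)
#' mp$bin_center[mp$values > 0]  # 12.5: offset 0 lives in bin [0, 25)
#' @export
metagene <- function(positions, anchors, window = 500, bin_size = 25) {
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0) {
    stop("`bin_size` must be > 0", call. = FALSE)
  }
  stopifnot_scalar_number(window, "window", positive = TRUE)
  if (window %% bin_size != 0) {
    stop("`window` must be a multiple of `bin_size`", call. = FALSE)
  }
  anchors <- as.data.frame(anchors)
  if (is.null(anchors$anchor)) {
    anchors$anchor <- anchors$annotated_tss
  }
  if (is.null(anchors$anchor) || is.null(anchors$strand)) {
    stop("`anchors` needs anchor (or annotated_tss) and strand columns",
         call. = FALSE)
  }
  if (is.numeric(positions) && is.null(dim(positions))) {
    positions <- data.frame(chrom = rep(anchors$chrom[1], length(positions)),
                            pos = positions)
  }
  if (!all(c("chrom", "pos") %in% names(positions))) {
    stop("`positions` needs chrom and pos columns", call. = FALSE)
  }

  n_bins <- as.integer(2L * window / bin_size)
  counts <- numeric(n_bins)
  n_items <- 0L
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    pos <- positions$pos[positions$chrom == a$chrom]
    off <- strand_dir(a$strand) * (pos - a$anchor)
    off <- off[off >= -window & off < window]
    n_items <- n_items + length(off)
    if (length(off) > 0L) {
      idx <- floor((off + window) / bin_size) + 1L
      counts <- counts + tabulate(idx, nbins = n_bins)
    }
  }
  edges <- seq(-window, window, by = bin_size)
  structure(
    list(
      bin_left = edges[-length(edges)],
      bin_right = edges[-1],
      bin_center = (edges[-length(edges)] + edges[-1]) / 2,
      values = counts / nrow(anchors),
      n_genes = nrow(anchors),
      bin_size = bin_size,
      n_items = n_items
    ),
    class = "metagene_profile"
  )
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("<metagene_profile> %d bins of %g nt over [%g, %g), %d genes, %d items\n",
              length(x$values), x$bin_size, min(x$bin_left), max(x$bin_right),
              x$n_genes, x$n_items))
  invisible(x)
}

#' Extract genomic fragment-center positions
#'
#' @param fragments A `chip_fragments` data frame.
#' @return Data frame with columns `chrom`, `pos`, suitable for
#'   [metagene()].
#' @export
fragment_centers <- function(fragments) {
  data.frame(chrom = fragments$chrom, pos = fragments$center)
}

#' Extract scRNA end positions
#'
#' @param reads An `scrna_reads` data frame.
#' @param end Which end to extract: `"five"` (capped 5' end) or `"three"`
#'   (pause-proximal 3' end).
#' @return Data frame with columns `chrom`, `pos`, suitable for
#'   [metagene()].
#' @export
scrna_end_positions <- function(reads, end = c("five", "three")) {
  end <- match.arg(end)
  data.frame(chrom = reads$chrom,
             pos = if (end == "five") reads$five_prime else reads$three_prime)
}

#' Detect promoter-proximal peaks in a metagene profile
#'
#' Smooths the profile with a centered moving average over
#' `smoothing_bins` bins and reports internal local maxima exceeding the
#' median of the smoothed profile, ordered by height. A plateau of equal
#' smoothed values flanked by lower values is reported once, at its center
#' bin. Endpoints are never peaks, so monotone profiles yield none. On
#' paired-end Pol II ChIP data this recovers the twin promoter peaks near
#' the TSS and ~+110 nt.
#'
#' @param profile A `metagene_profile` from [metagene()].
#' @param smoothing_bins Odd number of bins for the moving average
#'   (1 disables smoothing).
#' @return A data frame with columns `offset` (bin center, nt) and
#'   `height` (smoothed value), ordered by decreasing height; zero rows
#'   when no peak qualifies (e.g. an all-zero profile).
#' @export
detect_promoter_peaks <- function(profile, smoothing_bins = 3) {
  if (!inherits(profile, "metagene_profile")) {
    stop("`profile` must be a metagene_profile", call. = FALSE)
  }
  v <- profile$values
  if (length(v) == 0L) stop("empty profile", call. = FALSE)
  k <- as.integer(smoothing_bins)
  if (k < 1L || k %% 2L == 0L) {
    stop("`smoothing_bins` must be a positive odd integer", call. = FALSE)
  }
  # centered moving average; the window shrinks at the profile edges
  half <- (k - 1L) %/% 2L
  n <- length(v)
  sm <- vapply(seq_len(n), function(i) {
    mean(v[max(1L, i - half):min(n, i + half)])
  }, numeric(1))

  if (all(sm == 0)) {
    return(data.frame(offset = numeric(0), height = numeric(0)))
  }
  thr <- median(sm)

  # run-length encode so plateaus are handled as single candidate peaks
  r <- rle(sm)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peaks <- list()
  for (j in seq_along(r$values)) {
    if (j == 1L || j == length(r$values)) next # endpoints excluded
    if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L] &&
        r$values[j] > thr) {
      mid <- starts[j] + (r$lengths[j] - 1L) %/% 2L # plateau center bin
      peaks[[length(peaks) + 1L]] <-
        data.frame(offset = profile$bin_center[mid], height = r$values[j])
    }
  }
  if (length(peaks) == 0L) {
    return(data.frame(offset = numeric(0), height = numeric(0)))
  }
  out <- do.call(rbind, peaks)
  out <- out[order(-out$height), , drop = FALSE]
  rownames(out) <- NULL
  out
}
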