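# scRNA-based TSS and pause-site analysis.
#
# All offsets are TSS-relative with offset 0 at the TSS base and positive
# values downstream in the direction of transcription; minus-strand genes
# are mirrored before any histogramming.

# transcription-direction offset of genomic positions from an anchor
rel_offset <- function(pos, anchor, strand) {
  strand_dir(strand) * (pos - anchor)
}

sense_reads <- function(reads, gene) {
  reads[reads$chrom == gene$chrom & reads$strand == gene$strand, , drop = FALSE]
}

antisense_reads <- function(reads, gene) {
  reads[reads$chrom == gene$chrom & reads$strand != gene$strand, , drop = FALSE]
}

no_call <- function(gene_id, reason) {
  structure(list(gene_id = gene_id, called = FALSE, reason = reason),
            class = "tss_call")
}

#' Call a refined TSS from scRNA 5'-end positions
#'
#' The scRNA-derived TSS of a gene is the position with the highest number
#' of sense scRNA 5'-end hits within `window` nt of the annotated TSS
#' (default -500..+500). Ties are broken by the smallest absolute offset
#' from the annotated TSS, then by the upstream-most position (in the
#' direction of transcription). Genes with no sense 5' ends in the window
#' yield a no-call object (`called = FALSE`) rather than being dropped.
#'
#' @param reads An `scrna_reads` data frame (see [generate_scrna_reads()]);
#'   only reads on the gene's strand and chromosome are used.
#' @param gene A single-row [gene_models()] entry.
#' @param window Search half-width in nt (> 0).
#' @return An object of class `tss_call`: a list with `gene_id`, `called`,
#'   and, when called, `scrna_tss` (genomic coordinate), `support` (5'-end
#'   hits at that position), `offset_from_annotated` (signed nt in
#'   transcription direction), plus `strand` and `annotated_tss` carried
#'   over for downstream re-centering.
#' @examples
#' g <- gene_models("g1", "chr1", "+", 1000)
#' r <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
#'                 five_prime = c(997, 997, 1010), three_prime = 1040,
#'                 sense = TRUE)
#' call_tss(r, g)$offset_from_annotated  # -3
#' @export
call_tss <- function(reads, gene, window = 500) {
  stopifnot_scalar_number(window, "window", positive = TRUE)
  gene <- as_gene_models(gene)
  if (nrow(gene) != 1L) stop("`gene` must be a single gene model", call. = FALSE)
  rs <- sense_reads(reads, gene)
  off <- rel_offset(rs$five_prime, gene$annotated_tss, gene$strand)
  off <- off[abs(off) <= window]
  if (length(off) == 0L) {
    return(no_call(gene$gene_id, "no sense scRNA 5' ends in the search window"))
  }
  counts <- table(off)
  cand <- as.integer(names(counts))
  n_hits <- as.integer(counts)
  # argmax, ties by |offset| then upstream-most (most negative offset)
  ord <- order(-n_hits, abs(cand), cand)
  best <- cand[ord[1L]]
  structure(
    list(
      gene_id = gene$gene_id, called = TRUE,
      scrna_tss = gene$annotated_tss + strand_dir(gene$strand) * best,
      support = n_hits[ord[1L]],
      offset_from_annotated = best,
      strand = gene$strand,
      annotated_tss = gene$annotated_tss
    ),
    class = "tss_call"
  )
}

#' @export
print.tss_call <- function(x, ...) {
  if (!isTRUE(x$called)) {
    cat(sprintf("<tss_call> %s: no call (%s)\n", x$gene_id, x$reason))
  } else {
    cat(sprintf("<tss_call> %s: TSS at %d (offset %+d nt, support %d)\n",
                x$gene_id, x$scrna_tss, x$offset_from_annotated, x$support))
  }
  invisible(x)
}

#' Profile pause positions from scRNA 3' ends
#'
#' Histograms the 3'-end offsets of sense scRNAs downstream of a (typically
#' scRNA-called) TSS. Only reads whose 5' end lies within `gate` nt of the
#' TSS contribute, so that pause offsets are measured from the start they
#' actually initiated at; offsets are restricted to `1..max_offset`.
#'
#' @param reads An `scrna_reads` data frame.
#' @param tss Genomic coordinate of the TSS to measure from.
#' @param gene A single-row [gene_models()] entry (supplies strand/chrom).
#' @param max_offset Largest 3'-end offset retained (nt, > 0).
#' @param gate Admission half-width for the 5' end around `tss` (nt).
#' @return An object of class `pause_profile`: list with `gene_id`,
#'   `called`, `offsets`, `counts`, `modal_offset` (offset with the highest
#'   count; ties go to the smallest offset) and `n_reads`.
#' @examples
#' g <- gene_models("g1", "chr1", "+", 1000)
#' r <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
#'                 five_prime = 1000, three_prime = 1034, sense = TRUE)
#' pause_profile(r[rep(1, 10), ], 1000, g)$modal_offset  # 34
#' @export
pause_profile <- function(reads, tss, gene, max_offset = 200, gate = 2) {
  stopifnot_scalar_number(max_offset, "max_offset", positive = TRUE)
  gene <- as_gene_models(gene)
  if (nrow(gene) != 1L) stop("`gene` must be a single gene model", call. = FALSE)
  rs <- sense_reads(reads, gene)
  keep <- abs(rs$five_prime - tss) <= gate
  off <- rel_offset(rs$three_prime[keep], tss, gene$strand)
  off <- off[off >= 1 & off <= max_offset]
  if (length(off) == 0L) {
    return(structure(list(gene_id = gene$gene_id, called = FALSE,
                          reason = "no qualifying sense reads"),
                     class = "pause_profile"))
  }
  counts <- table(off)
  offsets <- as.integer(names(counts))
  n <- as.integer(counts)
  structure(
    list(
      gene_id = gene$gene_id, called = TRUE,
      offsets = offsets, counts = n,
      modal_offset = offsets[which.max(n)],
      n_reads = sum(n)
    ),
    class = "pause_profile"
  )
}

#' @export
print.pause_profile <- function(x, ...) {
  if (!isTRUE(x$called)) {
    cat(sprintf("<pause_profile> %s: no call (%s)\n", x$gene_id, x$reason))
  } else {
    cat(sprintf("<pause_profile> %s: modal 3' offset +%d nt (%d reads)\n",
                x$gene_id, x$modal_offset, x$n_reads))
  }
  invisible(x)
}

#' scRNA length distribution
#'
#' Frequency distribution of scRNA lengths, the 5'-to-3' distance of each
#' paired-end read in nt.
#'
#' @param reads A non-empty `scrna_reads` data frame.
#' @return A data frame with columns `length` and `count`; counts sum to
#'   `nrow(reads)`.
#' @export
length_distribution <- function(reads) {
  if (is.null(reads) || nrow(reads) == 0L) {
    stop("`reads` must be non-empty", call. = FALSE)
  }
  len <- abs(reads$three_prime - reads$five_prime)
  tab <- table(len)
  data.frame(length = as.integer(names(tab)), count = as.integer(tab))
}

#' Re-center metagene 5'-end profiles on scRNA-called TSSs
#'
#' Computes two aligned metagene profiles of sense scRNA 5'-end density -
#' one centered on each gene's annotated TSS, one re-centered on its
#' scRNA-called TSS - together with a sharpness metric, the fraction of
#' in-window 5'-end signal within `sharp_halfwidth` nt of the center.
#' Re-centering on called TSSs sharpens the profile whenever annotated
#' TSSs are offset from the true starts.
#'
#' Per gene, 5'-end counts in `-window..window` are normalized to a density
#' (so every gene with reads contributes equal weight) and densities are
#' averaged across genes. Genes whose TSS call is a no-call are skipped
#' with a message; reads whose `gene_id` has no entry in `calls` are an
#' error.
#'
#' @param reads An `scrna_reads` data frame with a `gene_id` column.
#' @param calls A list of [call_tss()] results covering every gene in
#'   `reads`.
#' @param window Profile half-width in nt.
#' @param sharp_halfwidth Half-width (nt) of the central band used for the
#'   sharpness metric.
#' @return A list of class `recentered_profiles`: `offsets`,
#'   `annotated` and `recentered` (mean per-offset densities),
#'   `sharpness_annotated`, `sharpness_recentered`, `n_genes`,
#'   `n_skipped` (no-call genes).
#' @export
recenter_profiles <- function(reads, calls, window = 100, sharp_halfwidth = 2) {
  stopifnot_scalar_number(window, "window", positive = TRUE)
  call_ids <- vapply(calls, function(x) x$gene_id, character(1))
  if (anyDuplicated(call_ids)) stop("duplicate gene ids in `calls`", call. = FALSE)
  missing <- setdiff(unique(reads$gene_id), call_ids)
  if (length(missing) > 0L) {
    stop("reads reference gene ids with no TSS call: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  names(calls) <- call_ids
  offsets <- seq.int(-window, window)

  density_for <- function(off) {
    off <- off[abs(off) <= window]
    if (length(off) == 0L) return(NULL)
    tabulate(off + window + 1L, nbins = 2L * window + 1L) / length(off)
  }

  ann <- list()
  rec <- list()
  n_skipped <- 0L
  for (gid in unique(reads$gene_id)) {
    call <- calls[[gid]]
    if (!isTRUE(call$called)) {
      n_skipped <- n_skipped + 1L
      next
    }
    rr <- reads[reads$gene_id == gid & reads$strand == call$strand, , drop = FALSE]
    if (nrow(rr) == 0L) next
    a <- density_for(rel_offset(rr$five_prime, call$annotated_tss, call$strand))
    r <- density_for(rel_offset(rr$five_prime, call$scrna_tss, call$strand))
    if (!is.null(a)) ann[[gid]] <- a
    if (!is.null(r)) rec[[gid]] <- r
  }
  if (n_skipped > 0L) {
    message(n_skipped, " gene(s) without a TSS call skipped in re-centering")
  }
  if (length(ann) == 0L || length(rec) == 0L) {
    stop("no genes with in-window 5'-end signal", call. = FALSE)
  }
  profile_ann <- Reduce(`+`, ann) / length(ann)
  profile_rec <- Reduce(`+`, rec) / length(rec)
  central <- abs(offsets) <= sharp_halfwidth
  sharp <- function(p) sum(p[central]) / sum(p)
  structure(
    list(
      offsets = offsets,
      annotated = profile_ann,
      recentered = profile_rec,
      sharpness_annotated = sharp(profile_ann),
      sharpness_recentered = sharp(profile_rec),
      n_genes = length(ann),
      n_skipped = n_skipped
    ),
    class = "recentered_profiles"
  )
}

#' Per-position base frequencies and information content
#'
#' Builds a position frequency matrix from equal-length DNA windows (e.g.
#' centered on annotated vs scRNA-called TSSs) and the per-position
#' information content in bits, `2 + sum(f * log2(f))`, the quantity that
#' rises at initiator-like motifs when windows are centered on true start
#' sites. `N` bases are excluded from the counts.
#'
#' @param sequences Character vector of equal-length A/C/G/T/N strings.
#' @return A list of class `pfm`: `freq` (4 x L matrix, rows A/C/G/T,
#'   columns summing to 1), `ic` (length-L information content, bits, in
#'   \[0, 2\]) and `n_sequences`.
#' @examples
#' m <- sequence_window_frequencies(c("TATA", "TATA", "TACA"))
#' m$ic[1]  # 2 bits: invariant column
#' @export
sequence_window_frequencies <- function(sequences) {
  if (length(sequences) == 0L) stop("`sequences` must be non-empty", call. = FALSE)
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("all sequences must have the same length", call. = FALSE)
  }
  L <- lens[1]
  mat <- matrix(unlist(strsplit(sequences, "")), ncol = L, byrow = TRUE)
  if (!all(mat %in% c("A", "C", "G", "T", "N"))) {
    stop("sequences may contain only A/C/G/T/N", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  counts <- vapply(seq_len(L), function(j) {
    col <- mat[, j]
    vapply(bases, function(b) sum(col == b), numeric(1))
  }, numeric(4))
  counts <- matrix(counts, nrow = 4, dimnames = list(bases, NULL))
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("every position needs at least one non-N base", call. = FALSE)
  }
  freq <- sweep(counts, 2, totals, "/")
  plogp <- ifelse(freq > 0, freq * log2(freq), 0)
  ic <- pmin(2, pmax(0, 2 + colSums(plogp)))
  structure(list(freq = freq, ic = ic, n_sequences = length(sequences)),
            class = "pfm")
}

#' Upstream antisense scRNA profile
#'
#' Divergent transcription produces antisense scRNAs whose paused 3' ends
#' sit well upstream of the gene TSS (~150 nt in MCF-7 cells). This
#' histograms 3'-end positions of reads antisense to the gene, restricted
#' to `1..window` nt upstream of `tss`, and estimates the center as the
#' signal-weighted mean upstream offset.
#'
#' @param reads An `scrna_reads` data frame.
#' @param tss Genomic TSS coordinate to measure upstream from.
#' @param gene A single-row [gene_models()] entry.
#' @param window Upstream search width in nt (> 0).
#' @return A list of class `antisense_profile`: `gene_id`, `called`,
#'   `upstream_offsets`, `counts`, `center` (weighted mean, positive nt
#'   upstream) and `n_reads`; or a no-call (`called = FALSE`) when no
#'   antisense read qualifies.
#' @export
antisense_profile <- function(reads, tss, gene, window = 500) {
  stopifnot_scalar_number(window, "window", positive = TRUE)
  gene <- as_gene_models(gene)
  if (nrow(gene) != 1L) stop("`gene` must be a single gene model", call. = FALSE)
  ra <- antisense_reads(reads, gene)
  # upstream of the gene = negative transcription-direction offset
  up <- -rel_offset(ra$three_prime, tss, gene$strand)
  up <- up[up >= 1 & up <= window]
  if (length(up) == 0L) {
    return(structure(list(gene_id = gene$gene_id, called = FALSE,
                          reason = "no antisense 3' ends upstream of the TSS"),
                     class = "antisense_profile"))
  }
  tab <- table(up)
  offs <- as.integer(names(tab))
  n <- as.integer(tab)
  structure(
    list(
      gene_id = gene$gene_id, called = TRUE,
      upstream_offsets = offs, counts = n,
      center = sum(offs * n) / sum(n),
      n_reads = sum(n)
    ),
    class = "antisense_profile"
  )
}
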