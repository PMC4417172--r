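#' Discrete offset distributions
#'
#' Small constructors for the discrete distributions used by the read
#' simulator: a distribution is a data frame with integer `offset` and
#' numeric `prob` columns, probabilities summing to 1.
#'
#' @param offsets Integer vector of support points (nt offsets).
#' @param probs Probabilities, one per offset; defaults to uniform.
#' @return A data frame with columns `offset` and `prob`.
#' @examples
#' offset_dist(33:35)                  # uniform over 33,34,35
#' offset_dist(0)                      # point mass at 0
#' offset_dist(c(-1, 0, 1), c(.2, .6, .2))
#' @export
offset_dist <- function(offsets, probs = rep(1 / length(offsets), length(offsets))) {
  if (length(offsets) == 0L) stop("`offsets` must be non-empty", call. = FALSE)
  if (length(probs) != length(offsets)) {
    stop("`probs` must have one entry per offset", call. = FALSE)
  }
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9) {
    stop("`probs` must be nonnegative and sum to 1 (within 1e-9)", call. = FALSE)
  }
  if (any(offsets != round(offsets))) stop("`offsets` must be integers", call. = FALSE)
  if (anyDuplicated(offsets)) stop("`offsets` must be unique", call. = FALSE)
  structure(
    data.frame(offset = as.integer(offsets), prob = as.numeric(probs)),
    class = c("offset_dist", "data.frame")
  )
}

sample_offset_dist <- function(dist, n) {
  if (nrow(dist) == 1L) {
    return(rep(dist$offset, n))
  }
  sample(dist$offset, n, replace = TRUE, prob = dist$prob)
}

#' Kinetic and positional parameters for scRNA simulation
#'
#' Bundles the parameters of the pausing model used by
#' [generate_scrna_reads()] and [simulate_pause_occupancy()]. Defaults
#' reproduce the basal MCF-7-like regime: pause 3' ends distributed
#' uniformly over +33..+35 nt, modest initiator-like start-site jitter,
#' divergent antisense transcription with 3' ends centered 150 nt upstream
#' of the TSS, and a 10-min pause half-life.
#'
#' @param k_init Initiation rate, events per gene copy per minute.
#' @param t_half Pause half-life in minutes; the pause-exit rate is
#'   `log(2) / t_half`.
#' @param pause_offset_dist [offset_dist()] over TSS-relative 3'-end offsets
#'   (nt downstream) of sense scRNAs.
#' @param tss_jitter_dist [offset_dist()] over 5'-end offsets around the true
#'   TSS (nt, signed in the direction of transcription).
#' @param antisense_center Center of the antisense 3'-end distribution, in nt
#'   upstream of the TSS (positive number).
#' @param antisense_spread Standard deviation (nt) of the antisense 3'-end
#'   distribution (Gaussian, rounded to integer offsets).
#' @param antisense_fraction Fraction of simulated reads that are antisense.
#' @param length_range Validity window (nt) for the simulated scRNA 5'->3'
#'   distance; draws outside it are rejected and redrawn.
#' @param seed Integer seed making generation deterministic, or `NULL`.
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params()
#' kinetic_params(t_half = 5, pause_offset_dist = offset_dist(34))
#' @export
kinetic_params <- function(k_init = 0.05,
                           t_half = 10,
                           pause_offset_dist = offset_dist(33:35),
                           tss_jitter_dist = offset_dist(-2:2, c(.05, .2, .5, .2, .05)),
                           antisense_center = 150,
                           antisense_spread = 40,
                           antisense_fraction = 0.3,
                           length_range = c(18L, 120L),
                           seed = NULL) {
  stopifnot_scalar_number(k_init, "k_init", positive = TRUE)
  stopifnot_scalar_number(t_half, "t_half", positive = TRUE)
  stopifnot_scalar_number(antisense_center, "antisense_center", positive = TRUE)
  stopifnot_scalar_number(antisense_spread, "antisense_spread")
  if (antisense_spread < 0) stop("`antisense_spread` must be >= 0", call. = FALSE)
  if (antisense_fraction < 0 || antisense_fraction > 1) {
    stop("`antisense_fraction` must be in [0, 1]", call. = FALSE)
  }
  for (d in list(pause_offset_dist, tss_jitter_dist)) {
    if (!inherits(d, "offset_dist")) {
      stop("distributions must be built with offset_dist()", call. = FALSE)
    }
  }
  if (length(length_range) != 2L || length_range[1] < 1 ||
      length_range[2] < length_range[1]) {
    stop("`length_range` must be c(min, max) with 1 <= min <= max", call. = FALSE)
  }
  structure(
    list(
      k_init = k_init, t_half = t_half,
      pause_offset_dist = pause_offset_dist,
      tss_jitter_dist = tss_jitter_dist,
      antisense_center = antisense_center,
      antisense_spread = antisense_spread,
      antisense_fraction = antisense_fraction,
      length_range = as.integer(length_range),
      seed = seed
    ),
    class = "kinetic_params"
  )
}

#' Sonication shear-bias parameters for ChIP fragment simulation
#'
#' Parameters of the two fragment-center models used by
#' [generate_chip_fragments()]:
#'
#' * `"empirical"` draws fragment centers from a two-component Gaussian
#'   location mixture of TSS-relative offsets (defaults: centers 0 and +110,
#'   sd 20 each, equal weights) - the twin promoter peaks as observed.
#' * `"mechanistic"` draws shear breakpoints uniformly over a promoter
#'   region and rejects any fragment with an endpoint strictly inside a
#'   protected footprint around the paused polymerase, probing the
#'   hypothesis that sonication is disfavored next to the paused complex.
#'
#' Fragment lengths are Gaussian (mean `fragment_length_mean`, sd
#' `fragment_length_sd`), truncated below at `fragment_length_min` by
#' rejection.
#'
#' @param mode `"empirical"` or `"mechanistic"`.
#' @param footprint_center TSS-relative center (nt) of the protected
#'   footprint (mechanistic mode).
#' @param footprint_halfwidth Half-width (nt) of the footprint; breakpoints
#'   strictly inside `(center - hw, center + hw)` are disallowed.
#' @param fragment_length_mean,fragment_length_sd,fragment_length_min
#'   Fragment length model in bp.
#' @param mixture_centers,mixture_sds,mixture_weights Empirical-mode mixture
#'   components (TSS-relative nt offsets).
#' @param region_halfwidth Half-width (nt) of the promoter region over which
#'   mechanistic breakpoints are drawn.
#' @param seed Integer seed or `NULL`.
#' @return An object of class `shear_bias_params`.
#' @examples
#' shear_bias_params()  # empirical twin-peak mixture
#' shear_bias_params(mode = "mechanistic", footprint_center = 34,
#'                   footprint_halfwidth = 14)
#' @export
shear_bias_params <- function(mode = c("empirical", "mechanistic"),
                              footprint_center = 34,
                              footprint_halfwidth = 14,
                              fragment_length_mean = 200,
                              fragment_length_sd = 50,
                              fragment_length_min = 50,
                              mixture_centers = c(0, 110),
                              mixture_sds = c(20, 20),
                              mixture_weights = c(0.5, 0.5),
                              region_halfwidth = 1000,
                              seed = NULL) {
  mode <- match.arg(mode)
  if (footprint_halfwidth < 0) stop("`footprint_halfwidth` must be >= 0", call. = FALSE)
  if (fragment_length_min <= 0 || fragment_length_mean <= 0) {
    stop("fragment lengths must be > 0", call. = FALSE)
  }
  if (length(mixture_centers) != length(mixture_sds) ||
      length(mixture_centers) != length(mixture_weights)) {
    stop("mixture component vectors must have equal length", call. = FALSE)
  }
  if (any(mixture_weights < 0) || abs(sum(mixture_weights) - 1) > 1e-9) {
    stop("mixture weights must be nonnegative and sum to 1", call. = FALSE)
  }
  if (any(mixture_sds < 0)) stop("mixture sds must be >= 0", call. = FALSE)
  stopifnot_scalar_number(region_halfwidth, "region_halfwidth", positive = TRUE)
  structure(
    list(
      mode = mode,
      footprint_center = footprint_center,
      footprint_halfwidth = footprint_halfwidth,
      fragment_length_mean = fragment_length_mean,
      fragment_length_sd = fragment_length_sd,
      fragment_length_min = fragment_length_min,
      mixture_centers = mixture_centers,
      mixture_sds = mixture_sds,
      mixture_weights = mixture_weights,
      region_halfwidth = region_halfwidth,
      seed = seed
    ),
    class = "shear_bias_params"
  )
}

#' Gene models
#'
#' A gene model records a gene's location, strand, the annotated TSS, and
#' the true TSS used by the simulators. `true_tss` may differ from
#' `annotated_tss` to exercise scRNA-based TSS re-centering, mimicking
#' annotation error.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param chrom Chromosome name(s), recycled.
#' @param strand `"+"` or `"-"`, recycled.
#' @param annotated_tss 0-based genomic coordinate of the annotated TSS.
#' @param true_tss 0-based coordinate of the true TSS; defaults to the
#'   annotated one.
#' @return A data frame of class `gene_models` with one row per gene.
#' @examples
#' gene_models("g1", "chr1", "+", 10000)
#' gene_models(c("g1", "g2"), "chr1", c("+", "-"), c(10000, 50000),
#'             true_tss = c(10005, 49990))
#' @export
gene_models <- function(gene_id, chrom = "chr1", strand = "+",
                        annotated_tss, true_tss = annotated_tss) {
  n <- length(gene_id)
  if (n == 0L) stop("at least one gene is required", call. = FALSE)
  if (anyDuplicated(gene_id)) stop("gene_id values must be unique", call. = FALSE)
  strand <- rep_len(strand, n)
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'", call. = FALSE)
  annotated_tss <- rep_len(annotated_tss, n)
  true_tss <- rep_len(true_tss, n)
  if (any(annotated_tss < 0) || any(true_tss < 0)) {
    stop("TSS coordinates must be >= 0", call. = FALSE)
  }
  structure(
    data.frame(
      gene_id = as.character(gene_id),
      chrom = rep_len(as.character(chrom), n),
      strand = strand,
      annotated_tss = as.integer(round(annotated_tss)),
      true_tss = as.integer(round(true_tss)),
      stringsAsFactors = FALSE
    ),
    class = c("gene_models", "data.frame")
  )
}

as_gene_models <- function(x) {
  need <- c("gene_id", "chrom", "strand", "annotated_tss")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop("expected a gene_models data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.null(x$true_tss)) x$true_tss <- x$annotated_tss
  x
}
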