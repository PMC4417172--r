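#' Simulate paired-end short capped RNA reads
#'
#' Generates strand-aware 5'/3'-end pairs of short capped RNAs (scRNAs) for a
#' set of genes. Sense reads start at the gene's *true* TSS plus an
#' initiator-like jitter drawn from `params$tss_jitter_dist`, and end at a
#' pause offset drawn from `params$pause_offset_dist` (nt downstream of the
#' true TSS, 33-35 nt by default). A configurable fraction of reads are
#' antisense, modelling divergent transcription: their 3' ends are Gaussian
#' around `params$antisense_center` nt upstream of the TSS (rounded to
#' integer offsets), and they point away from the gene.
#'
#' The 5'->3' distance of every simulated read must fall inside
#' `params$length_range` (default 18-120 nt, emulating gel size selection);
#' offending draws are rejected and redrawn, with an error after 1000
#' unsuccessful redraw rounds. Minus-strand genes are mirrored. Generation
#' is deterministic given `params$seed`.
#'
#' @param genes A [gene_models()] data frame (non-empty).
#' @param params A [kinetic_params()] object.
#' @param n_reads_per_gene Number of reads to simulate per gene (> 0).
#' @return A data frame of class `scrna_reads` with columns `gene_id`,
#'   `chrom`, `strand` (the read's strand), `five_prime`, `three_prime`
#'   (0-based genomic coordinates of the capped 5' end and the 3' end) and
#'   `sense` (logical, `FALSE` for divergent antisense reads).
#' @examples
#' g <- gene_models("g1", "chr1", "+", 10000)
#' p <- kinetic_params(tss_jitter_dist = offset_dist(0),
#'                     pause_offset_dist = offset_dist(34),
#'                     antisense_fraction = 0, seed = 1)
#' r <- generate_scrna_reads(g, p, 5)
#' all(r$five_prime == 10000) && all(r$three_prime == 10034)
#' @export
generate_scrna_reads <- function(genes, params, n_reads_per_gene) {
  genes <- as_gene_models(genes)
  if (nrow(genes) == 0L) stop("`genes` must be non-empty", call. = FALSE)
  if (!inherits(params, "kinetic_params")) {
    stop("`params` must be a kinetic_params object", call. = FALSE)
  }
  stopifnot_scalar_number(n_reads_per_gene, "n_reads_per_gene", positive = TRUE)
  n <- as.integer(n_reads_per_gene)
  lo <- params$length_range[1]
  hi <- params$length_range[2]

  with_seed(params$seed, {
    per_gene <- lapply(seq_len(nrow(genes)), function(i) {
      gene <- genes[i, ]
      dir <- strand_dir(gene$strand)
      n_anti <- rbinom(1L, n, params$antisense_fraction)
      n_sense <- n - n_anti

      out <- list()
      if (n_sense > 0L) {
        # joint rejection on (jitter, pause offset): distance must sit in the
        # length validity window
        draw <- function(k) {
          j <- sample_offset_dist(params$tss_jitter_dist, k)
          o <- sample_offset_dist(params$pause_offset_dist, k)
          cbind(j, o)
        }
        jo <- matrix(draw(n_sense), ncol = 2L)
        ok <- function(m) {
          len <- m[, 2] - m[, 1]
          len >= max(1L, lo) & len <= hi
        }
        rounds <- 0L
        bad <- !ok(jo)
        while (any(bad)) {
          rounds <- rounds + 1L
          if (rounds > 1000L) {
            stop("jitter/pause distributions cannot produce scRNA lengths in [",
                 lo, ", ", hi, "] after 1000 redraws", call. = FALSE)
          }
          jo[bad, ] <- draw(sum(bad))
          bad <- !ok(jo)
        }
        out$sense <- data.frame(
          gene_id = gene$gene_id, chrom = gene$chrom, strand = gene$strand,
          five_prime = gene$true_tss + dir * jo[, 1],
          three_prime = gene$true_tss + dir * jo[, 2],
          sense = TRUE, stringsAsFactors = FALSE
        )
      }
      if (n_anti > 0L) {
        centers <- redraw_until(
          n_anti,
          function(k) as.integer(round(rnorm(k, params$antisense_center,
                                             params$antisense_spread))),
          function(x) x >= 1L,
          what = "antisense 3'-end offset"
        )
        lens <- redraw_until(
          n_anti,
          function(k) sample_offset_dist(params$pause_offset_dist, k),
          function(x) x >= max(1L, lo) & x <= hi,
          what = "antisense read length"
        )
        three <- gene$true_tss - dir * centers
        out$anti <- data.frame(
          gene_id = gene$gene_id, chrom = gene$chrom,
          strand = if (gene$strand == "+") "-" else "+",
          five_prime = three + dir * lens,
          three_prime = three,
          sense = FALSE, stringsAsFactors = FALSE
        )
      }
      do.call(rbind, out)
    })
    reads <- do.call(rbind, per_gene)
    rownames(reads) <- NULL
    class(reads) <- c("scrna_reads", "data.frame")
    reads
  })
}

#' Simulate paired-end Pol II ChIP fragments
#'
#' Generates sonicated ChIP fragments around each gene's true TSS under one
#' of two shear models (see [shear_bias_params()]):
#'
#' * **empirical**: the TSS-relative fragment-center offset is drawn from a
#'   Gaussian location mixture (default components at 0 and +110 nt), then a
#'   truncated-Gaussian fragment length is placed symmetrically around it.
#' * **mechanistic**: both shear breakpoints are drawn (start uniform over
#'   the promoter region, end = start + length) and the fragment is rejected
#'   if either endpoint falls strictly inside the protected footprint
#'   `(footprint_center - hw, footprint_center + hw)`. Centers of the
#'   surviving fragments are depleted over the footprint and pile up on its
#'   flanks, reproducing twin peaks without two polymerases.
#'
#' Minus-strand genes are mirrored. Deterministic given `shear$seed`.
#'
#' @param genes A [gene_models()] data frame.
#' @param shear A [shear_bias_params()] object.
#' @param n_frags_per_gene Fragments to simulate per gene (> 0).
#' @return A data frame of class `chip_fragments` with columns `gene_id`,
#'   `chrom`, `start`, `end` (0-based half-open) and `center`
#'   (`floor((start + end) / 2)`).
#' @examples
#' g <- gene_models("g1", "chr1", "+", 10000)
#' s <- shear_bias_params(mixture_sds = c(0, 0), seed = 1)
#' f <- generate_chip_fragments(g, s, 100)
#' sort(unique(f$center - 10000))  # exactly the mixture centers 0 and 110
#' @export
generate_chip_fragments <- function(genes, shear, n_frags_per_gene) {
  genes <- as_gene_models(genes)
  if (nrow(genes) == 0L) stop("`genes` must be non-empty", call. = FALSE)
  if (!inherits(shear, "shear_bias_params")) {
    stop("`shear` must be a shear_bias_params object", call. = FALSE)
  }
  stopifnot_scalar_number(n_frags_per_gene, "n_frags_per_gene", positive = TRUE)
  n <- as.integer(n_frags_per_gene)

  draw_lengths <- function(k) {
    redraw_until(
      k,
      function(m) as.integer(round(rnorm(m, shear$fragment_length_mean,
                                         shear$fragment_length_sd))),
      function(x) x >= shear$fragment_length_min,
      what = "fragment length"
    )
  }

  if (shear$mode == "mechanistic" && shear$footprint_halfwidth > 0) {
    # fragments must be able to span the protected footprint; a footprint
    # wider than any drawable fragment leaves no valid spanning fragments
    max_len <- shear$fragment_length_mean + 6 * shear$fragment_length_sd
    if (2 * shear$footprint_halfwidth >= max_len) {
      stop("protected footprint is wider than any fragment the length ",
           "distribution can produce; no valid fragments", call. = FALSE)
    }
  }

  with_seed(shear$seed, {
    per_gene <- lapply(seq_len(nrow(genes)), function(i) {
      gene <- genes[i, ]
      dir <- strand_dir(gene$strand)
      len <- draw_lengths(n)

      if (shear$mode == "empirical") {
        comp <- sample.int(length(shear$mixture_weights), n, replace = TRUE,
                           prob = shear$mixture_weights)
        ctr <- as.integer(round(rnorm(n, shear$mixture_centers[comp],
                                      shear$mixture_sds[comp])))
        # place the fragment symmetrically around the mirrored genomic
        # center so the derived floor-center equals the drawn one exactly
        gc <- gene$true_tss + dir * ctr
        start <- gc - len %/% 2L
        end <- start + len
        return(data.frame(
          gene_id = gene$gene_id, chrom = gene$chrom,
          start = start, end = end,
          center = (start + end) %/% 2L,
          stringsAsFactors = FALSE
        ))
      } else {
        lo <- shear$footprint_center - shear$footprint_halfwidth
        hi <- shear$footprint_center + shear$footprint_halfwidth
        R <- shear$region_halfwidth
        ok <- function(m) {
          inside <- function(x) x > lo & x < hi
          !(inside(m[, 1]) | inside(m[, 2]))
        }
        draw <- function(k) {
          l <- draw_lengths(k)
          e1 <- as.integer(floor(runif(k, -R, R + 1)))
          cbind(e1, e1 + l)
        }
        ee <- matrix(draw(n), ncol = 2L)
        rounds <- 0L
        bad <- !ok(ee)
        while (any(bad)) {
          rounds <- rounds + 1L
          if (rounds > 1000L) {
            stop("could not place fragments outside the protected footprint ",
                 "after 1000 redraws", call. = FALSE)
          }
          ee[bad, ] <- draw(sum(bad))
          bad <- !ok(ee)
        }
        e1 <- ee[, 1]
        e2 <- ee[, 2]
      }

      # breakpoints (interval boundaries) mirror exactly on minus strand
      if (dir == 1L) {
        start <- gene$true_tss + e1
        end <- gene$true_tss + e2
      } else {
        start <- gene$true_tss - e2
        end <- gene$true_tss - e1
      }
      data.frame(
        gene_id = gene$gene_id, chrom = gene$chrom,
        start = start, end = end,
        center = (start + end) %/% 2L,
        stringsAsFactors = FALSE
      )
    })
    frags <- do.call(rbind, per_gene)
    rownames(frags) <- NULL
    class(frags) <- c("chip_fragments", "data.frame")
    frags
  })
}

#' Simulate a permanganate footprint lane profile
#'
#' Builds a densitometry lane trace over a TSS-relative window. Permanganate
#' oxidizes unpaired thymines, so only thymine positions inside the
#' transcription-bubble interval respond: their expected intensity is
#' `background + gain * bubble_fraction`, while every other position sits at
#' `background`. Gaussian noise (additive by default, multiplicative
#' optionally) is added and intensities are truncated at 0.
#'
#' @param region_start,region_end TSS-relative nt bounds of the lane
#'   (inclusive); `sequence` must cover exactly this range.
#' @param sequence DNA string (A/C/G/T/N) of length
#'   `region_end - region_start + 1`.
#' @param bubble_interval Length-2 numeric, the closed TSS-relative interval
#'   of the bubble; must lie within the region.
#' @param bubble_fraction Fraction of molecules carrying the bubble, in
#'   \[0, 1\].
#' @param background Background band intensity (arbitrary units).
#' @param gain Intensity gained per unit bubble fraction at responsive
#'   thymines.
#' @param noise_sd Noise standard deviation (intensity units for additive
#'   noise; relative units for multiplicative).
#' @param noise Noise model, `"additive"` or `"multiplicative"`.
#' @param seed Integer seed or `NULL`.
#' @return A data frame of class `lane_profile` with columns `offset`,
#'   `intensity`, `is_thymine`.
#' @examples
#' lane <- generate_lane_profile(-10, 60,
#'   sequence = paste(rep("T", 71), collapse = ""),
#'   bubble_interval = c(31, 51), bubble_fraction = 1, noise_sd = 0)
#' range(lane$intensity)
#' @export
generate_lane_profile <- function(region_start, region_end, sequence,
                                  bubble_interval, bubble_fraction,
                                  background = 2, gain = 10,
                                  noise_sd = 0,
                                  noise = c("additive", "multiplicative"),
                                  seed = NULL) {
  noise <- match.arg(noise)
  if (bubble_fraction < 0 || bubble_fraction > 1) {
    stop("`bubble_fraction` must be in [0, 1]", call. = FALSE)
  }
  offsets <- seq.int(region_start, region_end)
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (length(bases) != length(offsets)) {
    stop("`sequence` length (", length(bases), ") must match the region (",
         length(offsets), " nt)", call. = FALSE)
  }
  if (!all(bases %in% c("A", "C", "G", "T", "N"))) {
    stop("`sequence` may contain only A/C/G/T/N", call. = FALSE)
  }
  if (length(bubble_interval) != 2L || bubble_interval[1] > bubble_interval[2] ||
      bubble_interval[1] < region_start || bubble_interval[2] > region_end) {
    stop("`bubble_interval` must be [a, b] inside the region", call. = FALSE)
  }
  is_t <- bases == "T"
  in_bubble <- offsets >= bubble_interval[1] & offsets <= bubble_interval[2]
  expected <- rep(background, length(offsets))
  expected[is_t & in_bubble] <- background + gain * bubble_fraction

  with_seed(seed, {
    intensity <- if (noise_sd > 0) {
      if (noise == "additive") {
        expected + rnorm(length(expected), 0, noise_sd)
      } else {
        expected * (1 + rnorm(length(expected), 0, noise_sd))
      }
    } else {
      expected
    }
    lane_profile(offsets, pmax(0, intensity), is_t)
  })
}

#' Construct a lane profile object
#'
#' @param offsets Integer TSS-relative positions.
#' @param intensity Nonnegative band intensities, one per offset.
#' @param is_thymine Logical mask, `TRUE` where the probed strand has a T.
#' @return A data frame of class `lane_profile`.
#' @export
lane_profile <- function(offsets, intensity, is_thymine) {
  if (length(offsets) != length(intensity) ||
      length(offsets) != length(is_thymine)) {
    stop("offsets, intensity and is_thymine must have equal length", call. = FALSE)
  }
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  structure(
    data.frame(offset = as.integer(offsets), intensity = as.numeric(intensity),
               is_thymine = as.logical(is_thymine)),
    class = c("lane_profile", "data.frame")
  )
}

#' Simulate an initiation-block decay time course
#'
#' Models the loss of pausing signal after new initiation is blocked (e.g.
#' by triptolide): the expected reactivity at time `t` is
#' `2^(-t / t_half)` relative to the untreated (`t = 0`) point. Replicates
#' receive Gaussian noise, multiplicative (relative sd) by default or
#' additive, and values are truncated at 0.
#'
#' @param t_half Pause half-life in minutes (> 0).
#' @param times Nonnegative times (minutes), must include 0.
#' @param n_replicates Replicates per time point (>= 1).
#' @param noise_sd Noise standard deviation (relative for multiplicative).
#' @param noise `"multiplicative"` or `"additive"`.
#' @param seed Integer seed or `NULL`.
#' @return A data frame of class `decay_series` with columns `time`,
#'   `replicate`, `value` and attribute `normalized = FALSE`.
#' @examples
#' generate_decay_series(10, c(0, 10, 20), 1, noise_sd = 0)$value  # 1 .5 .25
#' @export
generate_decay_series <- function(t_half, times, n_replicates = 3,
                                  noise_sd = 0,
                                  noise = c("multiplicative", "additive"),
                                  seed = NULL) {
  noise <- match.arg(noise)
  stopifnot_scalar_number(t_half, "t_half", positive = TRUE)
  if (any(times < 0)) stop("`times` must be >= 0", call. = FALSE)
  if (!any(times == 0)) stop("`times` must include 0", call. = FALSE)
  stopifnot_scalar_number(n_replicates, "n_replicates", positive = TRUE)
  n_replicates <- as.integer(n_replicates)

  grid <- expand.grid(replicate = seq_len(n_replicates), time = as.numeric(times))
  expected <- 2^(-grid$time / t_half)
  with_seed(seed, {
    value <- if (noise_sd > 0) {
      if (noise == "multiplicative") {
        expected * (1 + rnorm(nrow(grid), 0, noise_sd))
      } else {
        expected + rnorm(nrow(grid), 0, noise_sd)
      }
    } else {
      expected
    }
    decay_series(grid$time, grid$replicate, pmax(0, value))
  })
}

#' Construct a decay series object
#'
#' @param time Times in minutes (must include 0, all >= 0).
#' @param replicate Replicate index per observation.
#' @param value Nonnegative reactivity values.
#' @param normalized Logical; `TRUE` once the mean `t = 0` value is 1.
#' @return A data frame of class `decay_series`.
#' @export
decay_series <- function(time, replicate, value, normalized = FALSE) {
  if (length(time) != length(value) || length(time) != length(replicate)) {
    stop("time, replicate and value must have equal length", call. = FALSE)
  }
  if (any(time < 0)) stop("times must be >= 0", call. = FALSE)
  if (!any(time == 0)) stop("the series must include t = 0", call. = FALSE)
  if (any(value < 0)) stop("values must be >= 0", call. = FALSE)
  if (normalized && abs(mean(value[time == 0]) - 1) > 1e-9) {
    stop("a normalized series must have mean t = 0 value 1", call. = FALSE)
  }
  structure(
    data.frame(time = as.numeric(time), replicate = as.integer(replicate),
               value = as.numeric(value)),
    normalized = normalized,
    class = c("decay_series", "data.frame")
  )
}

#' Simulate per-gene promoter enrichment scores
#'
#' Produces a gene table with strictly positive promoter Pol II enrichment
#' scores, used to exercise the top-fraction gene filter.
#'
#' @param n_genes Number of genes (> 0).
#' @param dist `"lognormal"` (default), `"uniform"`, or `"point"`.
#' @param meanlog,sdlog Log-normal parameters (`dist = "lognormal"`).
#' @param min,max Bounds for `dist = "uniform"` (must be > 0).
#' @param value Common score for `dist = "point"` (> 0).
#' @param seed Integer seed or `NULL`.
#' @return A data frame with columns `gene_id`, `score`.
#' @examples
#' generate_gene_table(5, dist = "point", value = 2)
#' @export
generate_gene_table <- function(n_genes, dist = c("lognormal", "uniform", "point"),
                                meanlog = 0, sdlog = 1,
                                min = 0.1, max = 10, value = 1,
                                seed = NULL) {
  dist <- match.arg(dist)
  stopifnot_scalar_number(n_genes, "n_genes", positive = TRUE)
  n_genes <- as.integer(n_genes)
  with_seed(seed, {
    score <- switch(dist,
      lognormal = rlnorm(n_genes, meanlog, sdlog),
      uniform = {
        if (min <= 0 || max <= min) stop("need 0 < min < max", call. = FALSE)
        runif(n_genes, min, max)
      },
      point = {
        if (value <= 0) stop("`value` must be > 0", call. = FALSE)
        rep(value, n_genes)
      }
    )
    data.frame(
      gene_id = sprintf("gene%0*d", nchar(n_genes), seq_len(n_genes)),
      score = score,
      stringsAsFactors = FALSE
    )
  })
}

#' Two-state occupancy simulator
#'
#' Continuous-time Monte-Carlo simulation of a gene copy switching between
#' an unoccupied state (entered at the pause-exit rate `log(2) / t_half`)
#' and a paused state (entered at the initiation rate `k_init`). Each of
#' `n_copies` copies starts unoccupied and is evolved by Gillespie sampling
#' for `t_end` minutes; the fraction of copies paused at `t_end` is
#' returned. For `t_end` much longer than `1 / (k_init + k_off)` this
#' converges to the closed-form steady state
#' [steady_state_occupancy()].
#'
#' @param k_init Initiation rate per copy per minute (> 0).
#' @param t_half Pause half-life in minutes (> 0).
#' @param n_copies Number of simulated gene copies (> 0).
#' @param t_end Simulated time in minutes; default 20 relaxation times.
#' @param seed Integer seed or `NULL`.
#' @return A list with `occupancy` (fraction of copies paused at `t_end`),
#'   `n_copies` and `t_end`.
#' @examples
#' sim <- simulate_pause_occupancy(0.0693, 10, 2000, seed = 1)
#' abs(sim$occupancy - 0.5) < 0.05
#' @export
simulate_pause_occupancy <- function(k_init, t_half, n_copies,
                                     t_end = NULL, seed = NULL) {
  stopifnot_scalar_number(k_init, "k_init", positive = TRUE)
  stopifnot_scalar_number(t_half, "t_half", positive = TRUE)
  stopifnot_scalar_number(n_copies, "n_copies", positive = TRUE)
  n_copies <- as.integer(n_copies)
  k_off <- log(2) / t_half
  if (is.null(t_end)) t_end <- 20 / (k_init + k_off)
  stopifnot_scalar_number(t_end, "t_end", positive = TRUE)

  with_seed(seed, {
    t_now <- numeric(n_copies)
    paused <- logical(n_copies)
    active <- rep(TRUE, n_copies)
    while (any(active)) {
      rate <- ifelse(paused[active], k_off, k_init)
      wait <- rexp(sum(active), rate)
      t_new <- t_now[active] + wait
      flip <- t_new <= t_end
      idx <- which(active)
      paused[idx[flip]] <- !paused[idx[flip]]
      t_now[idx] <- t_new
      active[idx[!flip]] <- FALSE
    }
    list(occupancy = mean(paused), n_copies = n_copies, t_end = t_end)
  })
}
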