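# Synthetic-data generators: degenerate-distribution contracts, sampling-law
# oracles (binomial/multinomial), rejection constraints and determinism.

test_that("degenerate jitter/pause distributions pin every read exactly", {
  g <- gene_models(c("gp", "gm"), "chr1", c("+", "-"), c(10000L, 20000L))
  reads <- generate_scrna_reads(g, point_params(34L), 10)

  plus <- reads[reads$gene_id == "gp", ]
  expect_equal(nrow(plus), 10L)
  expect_true(all(plus$five_prime == 10000L))
  expect_true(all(plus$three_prime == 10034L))
  expect_true(all(abs(plus$three_prime - plus$five_prime) == 34L))

  # minus-strand gene is mirrored: 3' end 34 nt upstream in genome space
  minus <- reads[reads$gene_id == "gm", ]
  expect_true(all(minus$five_prime == 20000L))
  expect_true(all(minus$three_prime == 20000L - 34L))
  expect_true(all(minus$strand == "-"))
})

test_that("empty gene list and invalid inputs error", {
  g <- make_genes(1)
  expect_error(generate_scrna_reads(g[0, ], point_params(), 10), "non-empty")
  expect_error(generate_scrna_reads(g, point_params(), 0), "> 0")
  # pause offsets below the length validity window can never be accepted
  bad <- kinetic_params(tss_jitter_dist = offset_dist(0L),
                        pause_offset_dist = offset_dist(5L),
                        antisense_fraction = 0, seed = 1)
  expect_error(generate_scrna_reads(g, bad, 5), "redraws")
})

test_that("empirical 3'-offset frequencies follow the multinomial law", {
  g <- make_genes(1, strand = "+")
  n <- 30000L
  reads <- generate_scrna_reads(g, default_pause_params(seed = 7L), n)
  off <- reads$three_prime - g$true_tss[1]
  counts <- table(factor(off, levels = 33:35))
  # 3-sigma multinomial band around n/3 per cell
  sigma <- sqrt(n * (1 / 3) * (2 / 3))
  expect_true(all(abs(as.integer(counts) - n / 3) < 3 * sigma))
  expect_equal(sum(counts), n)
})

test_that("antisense read count is binomial in the configured fraction", {
  g <- make_genes(1, strand = "+")
  n <- 10000L
  p <- kinetic_params(tss_jitter_dist = offset_dist(0L),
                      pause_offset_dist = offset_dist(33:35),
                      antisense_fraction = 0.3, seed = 11L)
  reads <- generate_scrna_reads(g, p, n)
  n_anti <- sum(!reads$sense)
  sigma <- sqrt(n * 0.3 * 0.7)
  expect_lt(abs(n_anti - n * 0.3), 3 * sigma)
  # antisense reads are on the opposite strand with 3' ends upstream
  anti <- reads[!reads$sense, ]
  expect_true(all(anti$strand == "-"))
  expect_true(all(anti$three_prime < g$true_tss[1]))
  expect_true(all(anti$five_prime > anti$three_prime))
})

test_that("sense 3'-offset distribution converges to the configured one (TVD)", {
  g <- make_genes(1, strand = "+")
  n <- 100000L
  reads <- generate_scrna_reads(g, default_pause_params(seed = 3L), n)
  emp <- table(factor(reads$three_prime - g$true_tss[1], levels = 33:35)) / n
  tvd <- 0.5 * sum(abs(as.numeric(emp) - 1 / 3))
  expect_lt(tvd, 0.02)
})

test_that("generators are bit-reproducible under a fixed seed", {
  g <- make_genes(2)
  p <- kinetic_params(seed = 42L)
  expect_identical(generate_scrna_reads(g, p, 200),
                   generate_scrna_reads(g, p, 200))
  s <- shear_bias_params(seed = 42L)
  expect_identical(generate_chip_fragments(g, s, 200),
                   generate_chip_fragments(g, s, 200))
  expect_identical(generate_decay_series(10, c(0, 5, 10), 3, 0.05, seed = 42L),
                   generate_decay_series(10, c(0, 5, 10), 3, 0.05, seed = 42L))
  expect_identical(generate_gene_table(100, seed = 42L),
                   generate_gene_table(100, seed = 42L))
  # and the seed does not leak into the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_scrna_reads(g, p, 10)); after <- runif(1)
  expect_identical(before, after)
})

test_that("empirical shear mode with point-mass mixture hits exactly two offsets", {
  g <- gene_models(c("gp", "gm"), "chr1", c("+", "-"), c(100000L, 300000L))
  s <- shear_bias_params(mixture_sds = c(0, 0), seed = 5L)
  frags <- generate_chip_fragments(g, s, 1000)
  for (i in 1:2) {
    f <- frags[frags$gene_id == g$gene_id[i], ]
    dir <- if (g$strand[i] == "+") 1L else -1L
    off <- dir * (f$center - g$true_tss[i])
    expect_setequal(unique(off), c(0L, 110L))
  }
})

test_that("mechanistic shear mode places no endpoint strictly inside the footprint", {
  g <- make_genes(1, strand = "+")
  s <- shear_bias_params(mode = "mechanistic", footprint_center = 34,
                         footprint_halfwidth = 14, seed = 9L)
  frags <- generate_chip_fragments(g, s, 5000)
  e1 <- frags$start - g$true_tss[1]
  e2 <- frags$end - g$true_tss[1]
  inside <- function(x) x > 20 & x < 48
  expect_false(any(inside(e1) | inside(e2)))
  # minus-strand gene: breakpoint offsets mirror exactly
  gm <- make_genes(1, strand = "-")
  fm <- generate_chip_fragments(gm, s, 5000)
  o1 <- gm$true_tss[1] - fm$end
  o2 <- gm$true_tss[1] - fm$start
  expect_false(any(inside(o1) | inside(o2)))
})

test_that("mechanistic center profile matches brute-force enumeration and is bimodal", {
  g <- make_genes(1, strand = "+")
  s <- shear_bias_params(mode = "mechanistic", footprint_center = 34,
                         footprint_halfwidth = 14,
                         fragment_length_mean = 120, fragment_length_sd = 20,
                         fragment_length_min = 50,
                         region_halfwidth = 400, seed = 13L)
  n <- 100000L
  frags <- generate_chip_fragments(g, s, n)
  centers <- frags$center - g$true_tss[1]

  # independent oracle: enumerate all (start, length) pairs over the same
  # discretized truncated-Gaussian length law and uniform start, keep pairs
  # with no endpoint strictly inside (20, 48), and accumulate center mass
  lens <- 50:220
  wl <- stats::dnorm(lens, 120, 20)
  wl <- wl / sum(wl)
  R <- 400L
  starts <- -R:R
  ctr_min <- min(starts) + min(lens) %/% 2L
  ctr_max <- max(starts) + max(lens) %/% 2L
  mass <- setNames(numeric(ctr_max - ctr_min + 1L),
                   as.character(ctr_min:ctr_max))
  inside <- function(x) x > 20 & x < 48
  for (k in seq_along(lens)) {
    e1 <- starts
    e2 <- starts + lens[k]
    ok <- !(inside(e1) | inside(e2))
    ctr <- e1[ok] + lens[k] %/% 2L
    idx <- ctr - ctr_min + 1L
    mass[idx] <- mass[idx] + wl[k]
  }
  mass <- mass / sum(mass)

  emp <- table(factor(centers, levels = ctr_min:ctr_max)) / length(centers)
  tvd <- 0.5 * sum(abs(as.numeric(emp) - mass))
  expect_lt(tvd, 0.05)

  # 25-bp binned center profile: the endpoint exclusion depletes the bands
  # half a fragment length to either side of the footprint, leaving local
  # maxima flanking +34 (the enumeration predicts the same W shape)
  brk <- seq(-150, 250, by = 25)
  binned <- as.numeric(table(cut(centers[centers >= -150 & centers < 250],
                                 brk, right = FALSE)))
  bin_of <- function(x) findInterval(x, brk)
  dip_l <- bin_of(34 - 120 / 2) # 120 = mean fragment length
  dip_r <- bin_of(34 + 120 / 2)
  expect_gt(binned[bin_of(34)], binned[dip_l])
  expect_gt(binned[bin_of(34)], binned[dip_r])
  expect_gt(max(binned[seq_len(dip_l - 1L)]), binned[dip_l])
  expect_gt(max(binned[seq(dip_r + 1L, length(binned))]), binned[dip_r])
})

test_that("a footprint wider than any fragment is rejected up front", {
  g <- make_genes(1)
  s <- shear_bias_params(mode = "mechanistic", footprint_center = 0,
                         footprint_halfwidth = 500,
                         fragment_length_mean = 100, fragment_length_sd = 10,
                         seed = 1)
  expect_error(generate_chip_fragments(g, s, 10), "wider")
})

test_that("lane generator is flat at zero fraction and linear by construction", {
  seqn <- lane_sequence(121)
  flat <- generate_lane_profile(-20, 100, seqn, c(31, 51), 0, background = 2,
                                gain = 10, noise_sd = 0)
  expect_true(all(flat$intensity == 2))

  full <- generate_lane_profile(-20, 100, seqn, c(31, 51), 1, background = 2,
                                gain = 10, noise_sd = 0)
  half <- generate_lane_profile(-20, 100, seqn, c(31, 51), 0.5, background = 2,
                                gain = 10, noise_sd = 0)
  hot <- full$is_thymine & full$offset >= 31 & full$offset <= 51
  expect_true(any(hot))
  expect_equal(full$intensity[hot] - 2, 2 * (half$intensity[hot] - 2))
  # non-T positions inside the bubble stay at background
  cold <- !full$is_thymine & full$offset >= 31 & full$offset <= 51
  expect_true(all(full$intensity[cold] == 2))
  expect_error(generate_lane_profile(-20, 100, seqn, c(31, 51), 1.2), "\\[0, 1\\]")
})

test_that("noiseless calibration series returns the generating line exactly", {
  seqn <- lane_sequence(121)
  fracs <- c(0, 0.25, 0.5, 0.75, 1)
  sig <- vapply(fracs, function(f) {
    lane <- generate_lane_profile(-20, 100, seqn, c(31, 51), f,
                                  background = 2, gain = 10, noise_sd = 0)
    quantify_region(lane, c(31, 51),
                    background_offsets = lane$offset[lane$is_thymine &
                                                       lane$offset < 31])
  }, numeric(1))
  fit <- fit_calibration(fracs, sig)
  n_t <- sum(generate_lane_profile(-20, 100, seqn, c(31, 51), 0,
                                   noise_sd = 0)$is_thymine[
               seq(31 + 21, 51 + 21)])
  expect_equal(fit$slope, 10 * n_t, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("decay generator obeys the halving law and replicate-mean CLT", {
  s <- generate_decay_series(10, c(0, 10, 20, 30), 1, noise_sd = 0)
  expect_equal(s$value, c(1, 0.5, 0.25, 0.125))
  expect_error(generate_decay_series(10, c(-1, 0), 1), ">= 0")
  expect_error(generate_decay_series(10, c(5, 10), 1), "include 0")

  noisy <- generate_decay_series(10, c(0, 10, 20), 3, noise_sd = 0.05,
                                 seed = 17L)
  for (t in c(0, 10, 20)) {
    truth <- 2^(-t / 10)
    m <- mean(noisy$value[noisy$time == t])
    expect_lt(abs(m - truth), 3 * 0.05 * truth / sqrt(3))
  }
})

test_that("noiseless decay is memoryless: v(t1 + t2) = v(t1) v(t2)", {
  th <- 7.3
  v <- function(t) generate_decay_series(th, c(0, t), 1, noise_sd = 0)$value[2]
  for (pair in list(c(3, 4), c(5, 12), c(0.5, 30))) {
    expect_equal(v(pair[1] + pair[2]), v(pair[1]) * v(pair[2]),
                 tolerance = 1e-12)
  }
})

test_that("gene table generator honours distribution, uniqueness, determinism", {
  pt <- generate_gene_table(10, dist = "point", value = 3, seed = 1)
  expect_equal(nrow(pt), 10L)
  expect_true(all(pt$score == 3))

  ln <- generate_gene_table(1000, dist = "lognormal", seed = 2)
  expect_equal(nrow(ln), 1000L)
  expect_false(anyDuplicated(ln$gene_id) > 0)
  expect_true(all(ln$score > 0))
})
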