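# Shared fixtures: small gene panels and default simulator settings used
# across the suite. Everything is generated in code under fixed seeds.

make_genes <- function(n = 4, chrom = "chr1", spacing = 100000L,
                       strand = rep(c("+", "-"), length.out = n),
                       true_shift = 0L) {
  tss <- 50000L + spacing * (seq_len(n) - 1L)
  gene_models(
    gene_id = sprintf("g%02d", seq_len(n)),
    chrom = chrom, strand = strand,
    annotated_tss = tss,
    true_tss = tss + rep_len(true_shift, n)
  )
}

# degenerate params: no jitter, point-mass pause, no antisense
point_params <- function(pause = 34L, seed = 1L) {
  kinetic_params(
    tss_jitter_dist = offset_dist(0L),
    pause_offset_dist = offset_dist(pause),
    antisense_fraction = 0,
    seed = seed
  )
}

default_pause_params <- function(seed = 1L, antisense_fraction = 0) {
  kinetic_params(
    tss_jitter_dist = offset_dist(0L),
    pause_offset_dist = offset_dist(33:35),
    antisense_fraction = antisense_fraction,
    seed = seed
  )
}

# a repeated 10-mer with thymines at fixed phase, long enough for any lane
lane_sequence <- function(n) {
  paste(rep_len(strsplit("ACGTTGCATT", "")[[1]], n), collapse = "")
}
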