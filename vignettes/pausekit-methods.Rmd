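---
title: "pausekit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pausekit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pausekit)
```

pausekit analyses promoter-proximal RNA polymerase II (Pol II) pausing
through four experimental readouts — short capped RNAs (scRNAs),
paired-end Pol II ChIP fragments, permanganate footprints, and
initiation-block decay kinetics — together with a synthetic-data module
that emulates all of them. This vignette describes the underlying models,
the parameters that matter, the numerical conventions, and what the
synthetic data can and cannot establish about real libraries.

## Coordinate conventions

Genomic intervals are 0-based half-open. All analysis is reported in
TSS-relative offsets: offset 0 is the TSS base, positive offsets run
downstream in the direction of transcription, and minus-strand genes are
mirrored before any histogramming or binning. On the minus strand the
mirroring is applied to interval *boundaries*, so shear breakpoints and
fragment centers map exactly (no off-by-one between strands). An scRNA's
"length" throughout is the 5′→3′ distance `|three_prime - five_prime|`
in nt.

## The scRNA model and TSS/pause calling

A paused polymerase holds a nascent RNA whose capped 5′ end marks the
transcription start and whose 3′ end marks the pause position. The
simulator (`generate_scrna_reads()`) draws, per sense read, a 5′ jitter
from a discrete initiator-like distribution (default: −2..+2 nt with
mass 0.05/0.2/0.5/0.2/0.05) and a 3′ pause offset from a discrete
distribution (default: uniform on +33..+35 nt, the predominant pause
window in human breast-cancer cells). A configurable fraction of reads
(default 0.3) model divergent transcription: antisense to the gene, 3′
ends Gaussian around 150 nt upstream (sd 40 nt, rounded to integers).
Simulated lengths must fall in an 18–120 nt validity window emulating gel
size selection; the bounds are a package choice — size-selection ranges
are rarely reported — and offending draws are redrawn (at most 1000
rounds, then an error, so an impossible configuration fails loudly
instead of looping).

`call_tss()` implements the standard refinement: the scRNA TSS is the
position with the most 5′-end hits within ±500 nt of the annotated TSS.
Ties — unaddressed in common practice — are broken deterministically by
smallest absolute offset, then by the upstream-most position. Genes
without in-window signal return a no-call object rather than being
dropped, and downstream metagenes skip and count them.

`pause_profile()` measures 3′-end offsets from a *called* TSS and admits
only reads whose 5′ end lies within ±2 nt of it. The gate (configurable)
ties the pause offset to the start the read actually initiated at, which
is what makes offsets comparable across genes after re-centering;
without it, annotation error would smear the pause distribution.

`recenter_profiles()` quantifies why re-centering matters: per gene, the
5′-end histogram is normalized to a density (each gene votes equally)
and averaged across genes, centered either on annotated or on called
TSSs. Sharpness is the fraction of in-window signal within ±2 nt of the
center. When true and annotated TSSs differ and jitter is symmetric,
re-centered sharpness is provably no smaller; the test suite asserts the
exact convolution result for a uniform −20..+20 annotation-offset panel
(flat 5/41 annotated sharpness vs 1 after re-centering).

`sequence_window_frequencies()` computes the position frequency matrix
and per-column information content `2 + Σ f log2 f` bits (`N` excluded
from counts), the quantity that rises at the initiator motif when
windows are centered on true start sites.

## The ChIP fragment-center model

Paired-end sequencing determines each immunoprecipitated fragment's
center directly, avoiding the single-end centering uncertainty that
blurs closely spaced peaks. The twin promoter peaks near offsets 0 and
+110 are modelled two ways (`shear_bias_params()`):

- **Empirical mode** (default) draws the center offset from a
  two-component Gaussian mixture (centers 0 and +110, sd 20 each, equal
  weights) and wraps a truncated-Gaussian fragment (mean 200 bp, sd
  50 bp, floor 50 bp — typical sonication, unreported in most studies)
  symmetrically around it. This reproduces the observed profile without
  committing to a mechanism.
- **Mechanistic mode** probes the speculative explanation that sonication
  is disfavored next to the paused complex: both shear breakpoints are
  drawn (start uniform over a ±1 kb promoter region by default) and any
  fragment with an endpoint strictly inside the protected footprint is
  rejected and redrawn. Brute-force enumeration of allowed breakpoint
  pairs (reproduced in the test suite) shows what this model actually
  yields: because fragments *spanning* the footprint remain allowed, the
  bin containing the footprint keeps full center density, and the
  depleted bands sit roughly half a fragment length to either side — a
  W-shaped profile with local maxima flanking the pause, not a dip at
  it. Only when the protected region is wide relative to the fragment
  length (spanning becomes rare) does the footprint itself empty of
  centers. The mode is therefore exposed as a hypothesis probe with both
  regimes reachable through `footprint_halfwidth`, and no claim is made
  that it quantitatively explains the +110 peak.

`metagene()` bins positions into contiguous `bin_size` bins over the
half-open window `[-window, window)` (25 bp for ChIP centers, 1 bp for
scRNA ends), mirrors minus-strand genes, and averages per-gene counts
across genes. Count conservation — `sum(values) * n_genes` equals the
number of in-window position/anchor pairs — holds exactly and is
asserted on every synthetic input. `detect_promoter_peaks()` smooths
with a centered 3-bin moving average (window shrinking at the edges),
and reports internal local maxima above the median of the smoothed
profile; a plateau reports its center bin once, and endpoints are never
peaks. Smoothing width and the median threshold are package choices,
exposed as parameters.

`promoter_enrichment()` is a density ratio — fragment centers per kb in
the half-open promoter `[tss - w, tss + w)` over the genome-wide center
density — and `select_top_fraction()` retains `ceiling(fraction * n)`
genes (default 0.30) with ties at the cut broken lexicographically by
gene id, making the filter deterministic and row-order invariant. Both
the ceiling and the tie rule are package choices; the promoter window
default (±500 nt) mirrors the TSS search window.

## Permanganate footprint quantitation

Permanganate oxidizes unpaired thymines, so the transcription bubble of
an engaged polymerase appears as elevated band intensities at T
positions. The lane simulator gives in-bubble T positions expected
intensity `background + gain × bubble_fraction` (defaults 2 and 10
arbitrary units; both configuration, not constants) and everything else
`background`, with additive truncated-at-zero Gaussian noise by default
(multiplicative optional) — densitometry noise models are essentially
never published, so additive is the simplest defensible default.

`quantify_region()` sums `max(0, intensity − mean(background))` over the
region's T positions. The per-position clamp avoids negative
contributions from noise; the sum (rather than a mean) means longer
bubbles score higher, matching gel-band intuition.
`call_reactive_region()` finds the longest run of consecutive thymines
above `background mean + z·sd` (z = 2 by default); with no explicit
background set, the background statistics are the median and MAD over
all T positions, which leaves a flat lane calling nothing. Non-T
positions never break a run, since permanganate is silent there.

`fit_calibration()` is ordinary least squares of aggregate signal
against bubble fraction; on noiseless generator series it recovers the
generating gain and background to machine precision with R² = 1,
grounding the occupancy logic: signal is read as proportional to the
fraction of occupied gene copies. `fold_change_test()` interprets
"independent samples t-test" as the pooled-variance Student's t
(two-sided), with Welch behind a flag, and defines the fold as the ratio
of group means (not a mean of per-replicate ratios) — both points where
published methods are usually silent, so pausekit states its choice. The
fold's SD comes from first-order error propagation of the group standard
errors. Zero-variance groups are flagged rather than producing NaN.
`occupancy_bound()` then converts a fold increase `F` on activation into
the upper bound `min(100, 100/F)` percent for pre-activation occupancy —
an upper bound, never an estimate, valid under signal–occupancy
proportionality and occupancy ≤ 100% after activation.

## Pause kinetics

Blocking new initiation (triptolide inhibits TFIIH) isolates pause exit:
the expected normalized signal is `2^(-t / t_half)`.
`normalize_series()` divides by the mean untreated (t = 0) value;
`fit_half_life()` regresses `ln(value)` on time by OLS with a free
intercept and returns `t_half = ln 2 / (−slope)`. Log-linear OLS was
chosen over nonlinear least squares for determinism and closed-form
testability (it is exact to 1e−9 on any noiseless exponential); an `nls`
refinement of the same model is available behind `method = "nls"`.
Replicates enter as separate points, so times with more replicates weigh
more. Zeros are floored at a configurable epsilon with a warning, and a
non-decaying series is an error with a diagnostic, not a negative
half-life. No plateau/baseline term is fitted: region quantitation has
already removed background, though the structure permits adding one.

The two-state occupancy relation
`occupancy = k_init / (k_init + ln 2 / t_half)` formalizes the
observation that promoter Pol II signal can reflect either stable
pausing or rapid turnover. `simulate_pause_occupancy()` checks it by
continuous-time Gillespie simulation of gene copies switching between
unoccupied and paused states (default horizon 20 relaxation times,
long enough that the start-state bias is below 1e−8); the suite verifies
agreement within binomial 3σ on a 3×3 rate grid at 10,000 copies.

## Problem sizes and what the tests show

The bundled analyses run at desk scale, sizes chosen so sampling error
is well below the assertions' tolerances while the full suite stays
fast: 30,000 sense reads for pause-offset recovery (multinomial 3σ ≈
80 counts per offset), 20,000 antisense reads for the upstream center
(CLT error 3·40/√20000 ≈ 0.85 nt against a ±2 nt check), 100,000
fragments per twin-peak run repeated over 100 seeds, 100 decay series
for the half-life median, and 10,000 copies for the occupancy
simulator.

Synthetic data establishes *internal correctness*: that each operation
recovers the parameters its generator used, under the generator's
assumptions. Real libraries violate those assumptions in known ways the
generators deliberately omit — mappability and alignment artifacts, PCR
duplication, sequence-dependent shear and oxidation preferences,
heterogeneous per-gene pause distributions, cap-state misclassification,
and gel compression in densitometry. Passing tests therefore validate
the estimators and their edge-case contracts, not the biology of any
particular dataset; applying the pipeline to aligned real data goes
through the same BEDPE/BED/TSV readers (`read_scrna_bedpe()`,
`read_chip_bedpe()`, `read_lane_tsv()`, …) with no code path unique to
simulation.

## Known limitations

- TSS calling picks a single modal position; genes with genuinely
  dispersed initiation are summarized by one coordinate plus its support.
- Peak detection is a smoothed-local-maximum heuristic suited to
  promoter-proximal twin peaks, not a general peak caller with input
  controls or FDR.
- The occupancy bound inherits the linearity assumption of the bubble
  calibration; strong background differences between in-vivo complexes
  and purified templates limit it to an upper bound.
- The mechanistic shear mode is a hypothesis probe (see above); its
  defaults do not, and are not claimed to, reproduce the empirical twin
  peaks quantitatively.
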