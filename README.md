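# dffchip

Fragment-level analysis of DFF footprinting libraries in R.

DNA Fragmentation Factor (DFF) is a blunt-cutting apoptotic endonuclease
that digests chromatin up to — but not into — the footprints of bound
proteins. Chromatin immunoprecipitation after DFF digestion (DFF-ChIP)
therefore yields paired-end fragments whose exact spans report the
protection footprint of the immunoprecipitated complex: ~70 bp over a bound
transcription factor such as CTCF, 65–85 bp over a preinitiation complex,
40–60 bp over engaged RNA polymerase II, ~147 bp over a nucleosome, and
160–210 bp composites when a factor contacts its neighbouring nucleosome.
`dffchip` implements the downstream computational stack for such libraries
as a tidyverse-native toolkit: every user-facing function takes a data
frame of fragments first and returns a tibble, so stages chain with the
pipe; matrix-valued results are light S3 objects with broom-style `tidy()` /
`glance()` methods and `autoplot()` renderers.

## What it computes

**Fragment I/O and bookkeeping** — `read_fragments()` ingests BEDPE, BED or
proper-paired SAM/BAM (one fragment per template, span = mate union, mate-1
strand); `dedup_fragments()` collapses PCR duplicates on the
(chrom, start, end, strand, 8-nt UMI) key; `filter_fragment_length()`
applies the 18–1000 bp template gate; `fragment_coverage()` /
`write_bedgraph()` build run-length coverage tracks;
`replicate_correlation()` computes the Pearson r of read sums in 10-kb
genomic bins.

**ChIP-Seq peak calling** (`call_peaks()` and its stages) — fragment
midpoints are counted in 25 bp bins; bins outside an 8-bin (200 bp)
occupied chain are removed; bins exceeding both neighbours become
candidates; scanning left to right, a candidate is kept when the minimum
bin between it and the last kept peak is < 60% of the smaller of the two
heights, or when the peaks are > 200 bp apart; each kept peak is refined by
least-squares fitting of A·exp(−(x−μ)²/2σ²) (400 bp window, σ started at
100 bp), and reported as a 10 bp summit line at height equal to the reads
within ±200 bp of μ. Library-size-normalized control subtraction, the
strict >75-read threshold and centromeric blocklisting
(`blocklist_centromeric_hg38()`) complete the pipeline.

**Center-cluster calling** (`call_center_clusters()`) — the
footprint-detection unit for sequence-specific factors: fragment centers
⌊(start+end)/2⌋ of gate-passing fragments are scanned with a fixed window
at 1-bp offsets; the highest-count window is accepted greedily (leftmost on
ties), overlapping windows are suppressed, and the process repeats until no
window holds the required depth. `cc_preset()` carries the published
parameterizations (native CTCF 50–75 bp/25 bp/depth 50; crosslinked CTCF
50–100/100/50; IRF 40–200/200/100); `expand_clusters()` widens clusters
(e.g. 25 → 125 bp) for motif discovery.

**fragMaps, heatmaps, profiles** — `fragmap()` builds the fragment-length ×
relative-position count matrix (a V-plot) around oriented anchors;
`coverage_heatmap()` builds per-region coverage rows sorted by a
signal window, returning the permutation for reuse on other datasets;
`center_profile()` histograms fragment centers of a size class and
normalizes to unit mass.

**Motif tools** — `scan_pwm()` scores both strands of a genome against a
PWM with log-odds and exact p-values from a dynamic program over the
discretized score lattice; `filter_sites_by_coverage()` keeps motif sites
fully spanned by at least 200 fragments (threshold and containment rule
configurable).

**Simulator** — `simulate_genome()` / `simulate_fragments()` plant
footprint classes with known truth (protection boundaries + Normal end
jitter, optional embedded motifs, nucleosome-ladder background, UMIs, PCR
duplicates), so every stage above is testable without downloads.

## Worked example

Simulate a CTCF-like library (100 planted 70-bp footprints with an embedded
motif on 2 Mb, 20% PCR duplicates), then run the fragment and cluster
stages:

```r
library(dffchip)
library(tibble)

spec <- footprint_spec("TF", c(70, 70), fragments_per_site = 60,
                       end_jitter_sd = 3, motif = "GAAACCGAAACCGAA")
sim <- simulate_genome(2e6, gc = 0.41, specs = list(spec),
                       n_sites = 100, seed = 42)
frags <- simulate_fragments(sim$truth, list(spec), sim$genome,
                            background_rate = 1, duplicate_rate = 0.2,
                            seed = 43) |>
  filter_fragment_length(18, 1000) |>
  dedup_fragments()
attr(frags, "n_duplicates")
#> [1] 1606

ccs <- call_center_clusters(frags, cc_preset("ctcf-native"))
head(ccs, 3)
#> # A tibble: 3 × 6
#>   chrom start   end center_count modal_center mean_center
#>   <chr> <int> <int>        <int>        <int>       <dbl>
#> 1 chrS  15909 15934           54        15929      15928.
#> 2 chrS  46108 46133           56        46129      46128.
#> 3 chrS  47970 47995           56        47988      47990.
nrow(ccs)
#> [1] 96

hits <- scan_pwm(sim$sequence, pwm_from_consensus(spec$motif),
                 p_thresh = 1e-6)
occupied <- filter_sites_by_coverage(hits, frags, min_reads = 20)
c(motif_sites = nrow(hits), occupied = nrow(occupied))
#> motif_sites    occupied
#>         108         107

anchors <- tibble(chrom = ccs$chrom, pos = ccs$modal_center, strand = "+")
fm <- fragmap(frags, anchors, x_half = 200, min_len = 18, max_len = 250)
glance(fm)
#> # A tibble: 1 × 3
#>   n_anchors   mass modal_length
#>       <int>  <int>        <int>
#> 1        96 408391           69
autoplot(fm)   # V-plot: a ~70 bp band centered on the planted footprints
```

96 of the 100 planted sites survive the depth-50 threshold in this draw
(per-site emission is 60 with some loss to the 50–75 bp gate), every
cluster's modal center lies within a few bp of a planted footprint, and the
fragMap's modal fragment length recovers the planted 70 bp protection.

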