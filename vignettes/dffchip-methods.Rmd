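---
title: "Methods and design of the dffchip toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the dffchip toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dffchip)
```

## The measurement model

DFF (DNA Fragmentation Factor) cuts both DNA strands bluntly and cannot cut
inside the footprint of a bound protein. A paired-end library prepared
after DFF digestion and immunoprecipitation therefore consists of fragments
whose two ends are, up to small enzymatic and end-repair noise, the
boundaries of a protected particle: a transcription factor (~70 bp), a
preinitiation complex (65–85 bp), an engaged polymerase (40–60 bp), a
nucleosome (~147 bp), or a composite of a factor touching its neighbouring
nucleosome (160–210 bp). Everything in this package works on that premise:
a fragment is a direct observation of one protection event, its *length*
identifies the particle class and its *center* localizes the particle.

All coordinates are 0-based half-open (BED convention) internally; 1-based
coordinates appear only in external displays. Fragment centers and interval
midpoints use `floor((start + end)/2)`, so even-length spans resolve
deterministically to the left.

## Fragment plumbing

`read_fragments()` reduces each template to the union of its mate spans and
records mate 1's strand; discordant or unmapped pairs are dropped with a
count, because the aligner configuration this models already enforces
concordant forward–reverse pairs. Deduplication keys on
(chrom, start, end, strand, UMI); libraries without UMIs fall back to the
coordinate key, and the retained copy is the first in canonical
(chrom, start, end) order so the operation is deterministic and idempotent.
Strand is part of the key by default — two templates with identical spans
on opposite strands are distinct molecules — with `use_strand = FALSE` to
collapse across strands.

Replicate agreement is measured as the Pearson correlation of read sums in
10-kb bins. A fragment is counted once, in the bin containing its start:
the quantity being correlated is reads per bin, not per-bp coverage, so a
long fragment does not vote in two bins. Identical bin vectors return
exactly 1 (short-circuited before the floating-point formula).

## The peak caller

The binned caller works on 25 bp midpoint-count bins and has six stages,
each exposed as a function so any stage can be inspected or replaced:

1. **Binning** (`bin_fragments()`): each fragment counts once, in the bin
   of its midpoint. Midpoint binning (rather than overlap binning) keeps
   "reads in the peak" an actual read count.
2. **Subtraction** (`subtract_background()`): control scaled by
   `lib_treatment/lib_control`, difference clamped at zero. Negative bins
   would poison the valley rule below, so clamping is applied immediately.
3. **Chain filter** (`chain_filter()`): bins not inside a run of ≥ 8
   consecutive occupied bins (200 bp) are zeroed. "Occupied" means strictly
   greater than a configurable floor (default 0).
4. **Candidates** (`find_candidate_bins()`): bins exceeding the left
   neighbour and at least the right neighbour. The asymmetric tie-break
   picks the leftmost bin of a plateau exactly once; chromosome edges count
   as zero, so a monotone rise ending at the edge still yields a candidate.
5. **Resolution** (`resolve_candidates()`): scanning left to right from the
   last accepted peak, the next candidate is kept if the minimum bin
   strictly between the two is < 60% of the smaller height, or if the
   separation exceeds 200 bp. Adjacent candidates (no bin strictly between)
   fail the valley rule by construction. The first candidate per chromosome
   seeds the scan. The 200 bp separation mirrors the 8-bin chain distance;
   both the fraction and the distance are `peak_params()` fields.
6. **Summit refinement** (`fit_summits()`): Levenberg–Marquardt
   least-squares of A·exp(−(x−μ)²/2σ²) over bins within 400 bp of the
   candidate center, started at A = bin height, μ = bin center, σ = 100 bp.
   The "400 bp width" is mapped to σ = 100 bp so that ±2σ spans the stated
   width; σ is free within [bin width, fit width]. Non-convergence falls
   back to the initialization values and flags the peak rather than losing
   it. `reads_in_peak` sums the bins whose centers fall in
   [μ − 200, μ + 200), on whatever track was fitted (subtracted counts if
   subtraction was used). The summit is reported as a 10 bp line centred on
   the rounded μ.

Filtering is strict: a peak needs *more than* 75 reads, and its 10 bp
summit line must not touch a blocklist interval. The bundled
`blocklist_centromeric_hg38()` carries six centromeric regions that survive
background subtraction; coordinates are stored 0-based half-open.

## The center-cluster caller

Footprints of sequence-specific factors are tightly positioned, so their
fragment centers pile into a few bp. `call_center_clusters()` gates
fragments by length, computes centers, and scores every window of width *w*
at 1-bp offsets by the number of centers it holds. Windows are accepted
greedily — highest count first, leftmost on ties — and all windows
overlapping an accepted one are suppressed, until no remaining window
reaches the depth threshold. Greedy maximal selection is the simplest
scheme that is simultaneously deterministic, non-overlapping, and complete
(no window disjoint from all accepted clusters reaches the depth); the test
suite verifies completeness by exhaustive scan on small instances. Each
cluster reports its center count, modal center (most frequent center,
leftmost on ties) and mean center.

The three presets encode the published use cases: `"ctcf-native"`
(50–75 bp, window 25, depth 50) for sharply positioned native footprints,
`"ctcf-xlink"` (50–100, 100, 50) where crosslinking broadens protections,
and `"irf"` (40–200, 200, 100) for composite factor/nucleosome peaks.
`expand_clusters()` re-centres a fixed target width on the floored cluster
midpoint (so 25 → 125 bp expansion is exact and symmetric up to the 1 bp
floor convention), clipping at chromosome ends with an explicit flag.

## fragMaps, heatmaps and profiles

A fragMap row is a fragment length, a column is a position relative to an
oriented anchor; every admitted (anchor, fragment) pair adds one count at
the fragment's length for every base its span covers inside
[−x_half, +x_half]. Accumulating per-bp occupancy (not a single midpoint
mark) reproduces the horizontal-bar appearance of published fragMaps, and
makes the matrix mass exactly the summed pair overlaps — an invariant the
tests check. Note the consequence: row mass is proportional to fragment
length × fragment count, so when comparing rows as "how many fragments of
this length", divide row sums by the row length (the acceptance
measurements do this). Matrices are emitted raw with the anchor count
attached, so per-anchor averages and any display scaling (`autoplot()`
exposes a gamma) are lossless downstream steps.

Minus-strand anchors mirror both the position axis and the fragment span:
base g maps to `pos − g`, so a fragment [start, end) occupies
[pos − end + 1, pos − start + 1). Relative coordinate 0 is the anchor base
itself.

Heatmaps are per-region coverage rows over an oriented span, binned at
10 bp by default, ordered by descending signal of a designated sort track
inside a sort window; ties keep input order (stable sort) and the
permutation is returned so a second dataset can be displayed in the order
established by the first. Center profiles histogram the centers of a
length class inside a relative span and normalize to unit mass; an empty
selection warns and returns zeros rather than NaN.

## Motif scanning

`scan_pwm()` adds a pseudocount of 1e-4 to every PWM cell, renormalizes,
and scores log2 odds against the background (the PWM's embedded background
if present, otherwise genome mononucleotide frequencies with add-one
smoothing so degenerate sequences keep all four probabilities positive).
Scores are discretized to a lattice of ~1000 steps spanning the score
range; the null distribution of the lattice score is computed exactly by
dynamic programming over positions under the background, and window
p-values are read off its tail. Reporting the lattice score (rather than
the un-discretized one) makes p-values exactly monotone in the reported
score. The minus strand is scanned with the reverse-complemented matrix
over the same coordinates; non-ACGT characters contribute zero log-odds
("score as background"). The default threshold of 1e-4 is the conventional
occurrence-scan default. Site selection by occupancy
(`filter_sites_by_coverage()`) counts fragments whose span fully contains
the motif — the natural reading of "reads covering the motif" — with
`rule = "overlap"` and `strict` flags for the laxer overlap rule and the
strict `>` threshold reading respectively, since both readings appear in
practice.

## The simulator

`simulate_genome()` plants non-overlapping protection sites (≥ 50 bp
apart) on a random background of specified GC, embedding each class's
motif at the site center; `simulate_fragments()` emits per-site fragments
whose ends are the protection boundaries plus rounded Normal(0, sd) noise
(default sd 3 bp — the feature classes are reported as size *ranges*, so a
small symmetric boundary noise is the minimal model consistent with them).
`jitter_mode = "center"` instead shifts whole fragments rigidly, preserving
the protection length exactly; this matches experiments whose question is
center localization rather than length dispersion. Background fragments
default to a nucleosome ladder (147·k, k ≤ 3, ±10 bp) because nucleosome-
sized protections dominate real digests; `background_lengths` overrides the
ladder when a test needs gate-passing background. UMIs are uniform random
8-mers; duplicates are exact copies (coordinates and UMI) injected at a
flat rate. All randomness flows from the single `seed` argument.

What the simulator does *not* model — sequence-dependent cut bias,
amplification bias beyond flat duplication, inter-site correlation,
chromatin heterogeneity — bounds what green tests mean: they demonstrate
algorithmic correctness against planted truth, not robustness to every
artefact of real libraries.

## Problem sizes and tolerances

The test and acceptance runs use desk-scale instances chosen to finish in
seconds while leaving no headroom for the checks to pass vacuously: 200
random tracks of ≤ 100 bins for oracle equivalence; 100 Poisson-resampled
Gaussians with amplitudes 50–500 for summit recovery (±12.5 bp, half a
bin); a 2 Mb genome with 100 planted sites of 60 fragments over 1/kb
background for cluster recovery (≥ 99 sites within 12 bp, zero clusters
farther than 100 bp from truth); 10,000-record brute-force comparisons for
the exact filters; and 1e-12 for the Pearson agreement. The genome-scale
counts reported for the original deep-sequencing datasets require those
libraries and an hg38 alignment and are out of desk-scale reach by design.

## Known limitations

The peak caller is a narrow-peak caller: no FDR estimation, no broad-peak
mode, no duplicate-aware shifting. Dense tracks are materialized per
chromosome, which is comfortable at megabase scale and acceptable but
memory-hungry at full genome scale. The center-cluster caller's greedy
selection is one reconstruction of the published "scanning window,
non-overlapping clusters" description; its placement and tie-breaks are
explicit and configurable precisely because the original is not specified
at that granularity. BigWig output is out of scope (bedGraph is the
canonical text output).
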