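---
title: "Quantifying Pol II pausing downstream of gene 3' ends: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Pol II pausing downstream of gene 3' ends: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polpause)
```

## The problem

RNA polymerase II does not stop transcribing at the annotated 3' end of a
gene (the EAG, end of annotated gene). After the nascent transcript is
cleaved, the polymerase remains engaged on the template and its ChIP-seq
occupancy stays elevated over a region downstream of the EAG before
termination. The shape of that region differs by 3'-end processing
mechanism: on replication-dependent core histone genes — short, intronless,
producing non-polyadenylated transcripts processed by the stem--loop/U7
machinery — occupancy collapses within a few hundred bp of the EAG, while on
genes whose transcripts are polyadenylated the signal is detectable 4--6 kb
downstream. Inhibiting polyadenylation increases downstream occupancy on
poly(A)+ genes but not on core histone genes, and reduces occupancy at their
promoters.

`polpause` implements the full computational side of such a study: gene-model
ingestion and isolation filtering, tag extension and binned coverage,
EAG-anchored orientation-normalised matrices, K-means partitioning of pause
patterns, per-gene pause quantification (extent, exponential decay length,
pausing indices, narrow/broad class), expression stratification, strandedness
of nascent transcription, and a two-condition perturbation contrast. A
parametric simulator with planted pause shapes provides ground truth for
every stage.

## Coordinates, anchors and orientation

All coordinates are 0-based half-open (BED convention); GTF input is read as
1-based inclusive and converted on ingestion, so BED round-trips bit-exactly.

Anchored windows are centred on the *annotation boundary*: the EAG point of a
plus-strand gene is its `end` coordinate and of a minus-strand gene its
`start` coordinate (symmetrically for the TSS). Window bins are laid out in
transcription orientation — column indices always increase downstream, with
the first downstream bin covering offsets `[0, bin_width)` from the anchor
point. With this convention, mirroring every interval of the genome
(`[s, e) -> [L - e, L - s)`) while flipping strands maps each gene's window
onto itself bin for bin, so the whole matrix stage is exactly
mirror-symmetric; the test suite asserts bitwise identity. The `tss`/`eag`
*fields* of a gene model report the first/last transcribed base
(`end - 1` on the boundary side), which is the conventional way the anchors
are quoted.

Neighbour distance for the isolation filter is the end-to-start gap between
transcription-unit intervals, strand-blind, because a downstream window is
contaminated by a neighbouring unit regardless of the neighbour's strand.
Overlapping units have distance 0. Since annotation sources do not state a
unique "non-redundant" rule, `collapse_transcripts()` defaults to the
longest transcript per gene symbol (deterministic tie-break by transcript
id) with an exon-union alternative; symbols mapping to several chromosomes
or strands are excluded, mirroring standard multi-locus probe-set exclusion.

## From tags to coverage

Single-end ChIP-seq tags mark only the end of each immunoprecipitated
fragment, so each tag is extended from its 5' end in read orientation to
200 bp (tags already longer keep their native length) and clipped at
chromosome edges. Coverage is the exact per-base fragment depth, stored
run-length encoded; a bin's value is the mean per-base depth over the bin,
which conserves base pairs exactly: `sum(bins) * bin_width` equals the summed
fragment lengths in raw mode, a property asserted exactly in the tests.
`rpm` scaling (`1e6 / total fragments`) is applied last and is the default,
so signal and mock tracks are co-plottable. No mock subtraction is applied
anywhere; the mock is overlaid (profiles) or used as a detection threshold
and normaliser, never subtracted from the signal.

Anchored matrices are extracted from the per-base representation, not from a
genome-wide grid, so windows centre exactly on each anchor whatever its
offset. Out-of-chromosome bins are zero-filled and the row flagged. The
scaled-gene ("metagene") matrix divides each body into `n_body_bins = 100`
equal proportional intervals between fixed-width flanks; both the fixed-width
EAG/TSS views and the proportional body view are provided because average
gene figures can be drawn either way and the underlying studies do not pin
the choice down.

## Clustering pause patterns

K-means is run on the EAG ± 4 kb signal matrix with Euclidean distance and
*no row scaling* by default: the pause classes separate partly by absolute
occupancy, which per-row standardisation would erase. The implementation is
Lloyd's algorithm with k-means++ seeding, 50 restarts under one seeded RNG
stream (best inertia wins, earlier restart breaks ties), and empty clusters
re-seeded from the point farthest from its centroid. `k` is fixed a priori
per analysis (2 for a narrow/broad split, 4 for the finer pattern
partition), as is standard for this kind of pattern clustering; no automatic
model selection is attempted. Fixed seeds give bitwise-identical partitions,
and planted-class recovery is scored with the adjusted Rand index (checked
in tests against brute-force pair counting and an independent
implementation).

## Per-gene pause quantification

*Detection threshold.* "Detectable" occupancy is operationalised against the
mock: per gene, the mock row's mean and SD define a threshold
`mean + 2 SD`; an all-zero mock row falls back to the pooled global mock
level (flagged). The signal row is smoothed with a 3-bin centred running
mean (partial windows at the edges), and the **pause extent** is the
distance from the EAG to the start of the first downstream bin whose
smoothed value falls below threshold — 0 if the first bin is already below,
capped at the flank if none is. Raising the threshold can only shorten the
extent, and scaling signal and background together leaves it unchanged
(both properties are tested).

*Decay length.* Downstream decay is summarised by fitting
`log(signal - floor)` against distance by least squares over the downstream
bins within the extent; `lambda = -1/slope`. Two numerical choices matter:

- **Fit start.** Extended-fragment coverage is the read-start intensity
  convolved with a ~2-extension-length box. Beyond one extension length from
  the anchor the convolved exponential tail is exactly proportional to
  `exp(-d/lambda)` (the kernel contributes a constant factor), but the bins
  closer in mix body and pause signal and flatten the apparent slope. The
  pipeline therefore starts the fit `extension_bp` past the anchor
  (`fit_from_bp`); with unconvolved input (the noiseless expected-coverage
  path) the default fit from the anchor recovers planted constants to
  machine precision, because a binned exponential is still exactly
  log-linear in the bin midpoints.
- **Floor.** The subtracted floor is the *signal* track's pooled intergenic
  level (mean coverage outside gene neighbourhoods), not the mock level: the
  two tracks are rpm-normalised separately, so the mock's rpm value is not
  the signal track's additive background, and subtracting it biases
  `lambda` downward. The mock enters detection (above); the signal's own
  intergenic floor enters subtraction.

Fits with fewer than three usable bins (positive residual, past the fit
start) or a non-negative slope are reported as undefined rather than as
errors; at the study depth this leaves roughly 80--90% of narrow-class genes
with a defined `lambda`, and class medians are taken over the defined
subset.

*Shape classes.* `none` if the extent is 0, `narrow` if it is at most
1000 bp, else `broad`. The 1 kb boundary sits between the region where
core-histone downstream signal is validated positive (+0.1--0.3 kb) and
negative (+1.5--2 kb), and below the poly(A)+ positive region; there is no
quantitative published definition of "pause", so this boundary is a declared
package decision, as are the threshold and smoothing choices above.

*Pausing indices.* The TSS index is the mean density in
`[TSS - 50, TSS + 300)` over the mean body density
(`[TSS + 300, EAG - 500)`); the downstream index uses `[EAG, EAG + 4000)`
over the same body. A pseudocount of 0.01 rpm in the denominators guards
silent bodies; genes too short to host a body window (under 800 bp with the
default trims — including typical core histone genes) get undefined indices,
which mirrors the fact that promoter assays are not feasible on genes
shorter than the sonication fragment length.

## The perturbation contrast

The polyadenylation-inhibition comparison evaluates a qPCR-like region
panel: for core-histone genes regions I (+100--300) and II (+1500--2000)
downstream of the EAG, for other genes I (+500--1000), II (+2000--3000) and
III (+4000--5000), plus a promoter region (−50..+300 around the TSS, skipped
for genes under 500 bp). Two numerical safeguards make region values usable
at sequencing depth:

- the mock denominator is averaged over the region padded by 2 kb per side
  (`mock_pad_bp`): the mock is locally flat non-specific background, and a
  200-bp window holds so few mock fragments that zero-count windows would
  otherwise hit the `epsilon` floor and explode single ratios;
- each track's region density is first divided by its own pooled intergenic
  level (`floor_normalize`). rpm is library-size normalised, so when a
  condition changes total genome-wide occupancy the raw rpm of *unchanged*
  regions shifts too, and a separately sequenced mock cannot cancel that.
  Fold enrichment over the track's own background is invariant to library
  size and is the sequencing analogue of a percent-input qPCR value; on this
  scale a planted two-fold downstream increase measures as 2.0.

Per-gene treated/untreated ratios are summarised per class and region by the
geometric mean with a seeded percentile bootstrap (1000 resamples) on log
ratios. The geometric mean is used because ratio noise is multiplicative:
the arithmetic mean of per-gene ratios is inflated by the squared
coefficient of variation of the denominator (10--25% at these depths), which
would shift null comparisons visibly away from 1. Undefined values, and
zero numerators or denominators, propagate as undefined and are excluded
from summaries with their count reported.

## The synthetic model

Per-base occupancy intensity of a gene is

```
background
+ tss_amplitude * exp(-(t - tss_offset)^2 / (2 * tss_sd^2))   # promoter peak
+ body_level                                                   # in the body
+ pause_amplitude * exp(-d / lambda)   for 0 < d <= cap        # 3' pause
```

with `t` the transcription-orientation offset from the TSS and `d` the
offset past the EAG, evaluated at base centres (so the model is exactly
mirror-symmetric between strands). Defaults, in arbitrary occupancy units
per bp: background 0.02, body 0.5, TSS peak 8 (offset +30 bp, SD 150 bp —
the promoter-proximal stall position and a realistic ChIP peak width), pause
amplitude 5. The two planted classes fix the decay: narrow/core-histone-like
`lambda = 250 bp`, cap 1 kb; broad/poly(A)+-like `lambda = 1500 bp`, cap
8 kb (signal extinguished by 4--6 kb, matching the observed broad-pause
range). An exponential is the simplest monotone shape consistent with a
sharp drop at one extreme and a multi-kb tail at the other, and makes
`lambda` a recoverable ground-truth parameter. Amplitudes are fixed per
class; expression-table values get an independent lognormal spread, since
the coupling between expression level and occupancy is not part of the
model.

Genome layout: genes alternate strands at 20--30 kb spacing (safely inside
the 4-kb isolation regime) across two chromosomes; a clustered-histone
layout is obtained with `spacing_range = c(800, 1000)`. Gene lengths are
class-specific — core-histone 400--800 bp and intronless, poly(A)+ 5--8 kb
with 2--5 exons — matching the real size contrast and keeping the promoter
peak of long genes outside the EAG ± 4 kb window, as in the isolated-gene
regime the analysis targets.

Reads are 32-bp tags whose 5' positions are Poisson-sampled proportionally
to intensity (total count Poisson around the target depth), assigned random
strands for ChIP/mock and the gene's strand for gene-derived nascent tags;
they are then extended by the *pipeline*, exactly like real tags. The mock
track is pure background at matched depth. The default nascent background is
zero, encoding the observation that downstream-of-EAG nascent transcription
is entirely sense. The cordycepin-like condition multiplies poly(A)+ pause
amplitudes by `gamma` (default 2) and their TSS amplitudes by `delta`
(default 0.5), leaves histone genes untouched, and scales the treated read
depth by the total intensity-mass ratio — a constant IP recovery fraction,
which is what makes absolute cross-condition comparison meaningful at all.

What the simulator does *not* emulate: sequence context and mappability,
PCR duplicates, GC bias, overlapping or nested genes, antisense promoter
transcription, expression--occupancy coupling, and biological replicate
variability. Passing the planted-recovery suite therefore demonstrates that
the estimators are correct and well-calibrated for the modelled
phenomenology, not that they are robust to every artefact of real ChIP-seq.

## Problem sizes and determinism

The validation scenario used throughout the tests and the acceptance script
is 200 genes (half per class) at ~200 signal tags per gene with a
matched-depth mock — about 40k tags per track over ~5 Mb — which runs the
full pipeline in seconds and leaves each validation check (cluster recovery
ARI >= 0.9, class-median decay within 20%, >= 95% correct shape classes,
perturbation CIs) a comfortable margin at that depth. Every random step —
layout, sampling, K-means restarts, bootstrap — derives from a single seed,
and re-running any analysis with the same config and seed reproduces every
output file byte for byte.

## Known limitations

- The narrow/broad boundary, detection threshold and smoothing width are
  declared operationalisations; published work gives no quantitative
  definition of "pause", so absolute extents should be read relative to
  these settings.
- Decay fitting assumes a single-exponential tail; composite or plateaued
  termination profiles will fit poorly (flagged undefined rather than
  mis-reported where the fit degenerates).
- The isolation filter guarantees uncontaminated windows but biases the
  gene universe against dense regions (notably histone clusters, analysed
  separately at ± 1 kb for that reason).
- Terminator-sequence analysis (G-rich/CoTC motifs) is out of scope; no
  sequence-level signal is modelled or scanned.
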