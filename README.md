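# polpause

Genome-wide quantification of RNA polymerase II (Pol II) pausing downstream
of the 3' end of annotated genes (EAGs) from ChIP-seq tags.

After the nascent transcript is cleaved at a gene's 3' end, Pol II stays
engaged on the template and its ChIP occupancy remains elevated over a
region downstream of the EAG before termination. The shape of that region
tracks the 3'-end processing mechanism: core histone genes (short,
intronless, non-polyadenylated transcripts) show a *narrow* pause that
collapses within a few hundred bp, while poly(A)+ genes show a *broad*
pause detectable 4–6 kb downstream, which polyadenylation inhibition
amplifies. `polpause` is for genomicists who want to measure, classify and
compare these patterns reproducibly — and to validate every step against a
generator with planted ground truth.

## What it computes

For a signal (Pol II) track, a mock control track and a gene annotation:

- **Isolated gene universe** — transcript collapsing and a strand-blind
  filter keeping genes ≥ 4 kb from any neighbouring transcription unit.
- **Coverage** — 32-bp tags extended to 200 bp in read orientation; exact
  per-base fragment depth, 50-bp binned values (mean depth, conserving
  base pairs exactly), rpm normalisation; bedGraph export.
- **Anchor matrices** — genes × bins occupancy around the TSS or EAG (or
  with proportionally scaled bodies), always oriented so downstream is
  rightward.
- **Pause clustering** — seeded k-means++ / Lloyd partition of EAG ± 4 kb
  patterns with per-cluster profiles and sizes; adjusted Rand index against
  any reference labelling.
- **Pause metrics** — per gene: detection extent against a
  `mock mean + 2 SD` threshold, exponential decay length λ from a
  log-linear fit (`signal ∝ exp(−d/λ)` downstream of the EAG), TSS and
  downstream pausing indices, and a `narrow` / `broad` / `none` call
  (boundary 1 kb).
- **Stratification** — expression-table ingestion (replicate means,
  low-intensity and multi-locus filters), top-expressed selection,
  per-cluster expression summaries, and sense/antisense fractions of
  stranded nascent (GRO-seq-like) reads downstream of EAGs.
- **Perturbation contrast** — mock-normalised fold enrichments over a
  qPCR-style region panel (histone: +0.1–0.3 / +1.5–2 kb; poly(A)+:
  +0.5–1 / +2–3 / +4–5 kb; promoter −50..+300) compared between two
  conditions with bootstrap confidence intervals on the geometric mean
  ratio.
- **Synthetic data** — a parametric occupancy model
  (`background + TSS Gaussian + body plateau + pause_amplitude·exp(−d/λ)`
  capped per class) sampled into 32-bp tags with full truth tables, plus a
  cordycepin-like two-condition mode.

## Worked example

Simulate a study-like dataset (60 isolated genes, half core-histone-like
with planted λ = 250 bp, half poly(A)+-like with λ = 1500 bp, ~200 tags per
gene) and run the full analysis:

```r
library(polpause)

sc  <- simulate_scenario(n_genes = 60, seed = 42)
cfg <- analysis_config(sc$reads$signal, sc$reads$mock,
                       sc$genome$genes, sc$genome$chrom_sizes,
                       truth = sc$genome$truth, expression = sc$expression,
                       k = 2, seed = 42)
res <- run_eag_analysis(cfg)

res$clusters
#> ClusterResult: k=2, n=60, inertia=3.5e+08, seed=42
#>   sizes: 35/25
res$manifest$planted_ari
#> [1] 1

m <- merge(res$metrics, sc$truth[, c("gene", "pause_class")])
aggregate(cbind(pause_extent_bp, decay_length_bp) ~ pause_class, m,
          median, na.action = na.pass, na.rm = TRUE)
#>   pause_class pause_extent_bp decay_length_bp
#> 1           H             450         253.582
#> 2          PA            2400        1707.246
table(planted = m$pause_class, called = m$shape_class)
#>        called
#> planted broad narrow none
#>      H      0     34    1
#>      PA    25     0    0
```

The two planted classes are recovered perfectly by k-means (ARI = 1), the
median fitted decay lengths sit close to the planted 250 / 1500 bp, and the
narrow/broad calls match the planted classes. Giving `out_dir =` in the
config additionally writes the artifact bundle (kept genes, matrices,
cluster tables, metrics, profiles, manifest); re-running with the same
config and seed reproduces it byte for byte.

A thin command-line wrapper is installed with the package
(`system.file("cli/polpause.R", package = "polpause")`) with
`simulate`, `run-all` and `perturb` subcommands over the same functions.

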