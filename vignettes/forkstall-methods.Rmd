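---
title: "Methods: models, estimators and design choices in forkstall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in forkstall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forkstall)
```

## Scope and model

`forkstall` analyses multi-timepoint BrdU-Seq from synchronised cells. The
underlying picture: during a BrdU pulse, replicated regions acquire uniform
labelled coverage; where forks pause in a fraction of cells, labelled reads
over-accumulate locally, producing a peak. Pausing is short-lived, so a
hotspot's enrichment is confined to (essentially) one timepoint — the
package's transience model. Downstream questions are about context: is the
hotspot inside a transcribed gene, and does the fork there travel with or
against transcription (codirectional vs head-on, with genes replicated from
both ends called undetermined)? Do hotspots coincide with rearrangement
breakpoints and fragile sites more than chance? Coordinates are BED-style
0-based half-open throughout; 1-based structural-variant positions are
converted on read, so no mixed conventions exist internally.

## Peak calling

`call_peaks()` is a deliberately simple Poisson scan, not a re-implementation
of a full fragment-model caller: the package's contribution is the
multi-timepoint framework around the caller, and on binned synthetic
count data a local-lambda Poisson test is the appropriate null. For each bin
the background rate is the maximum of the input-track mean over a 1-kb
window, a 10-kb window, and the genome-wide mean (after scaling both
libraries to their common mean depth); taking the maximum makes the test
conservative where the input is locally noisy. Bins with
$P(\mathrm{Pois}(\lambda) \ge s) < 10^{-5}$ (computed through the gamma-tail
identity, so fractional depth-scaled counts are handled continuously) and
fold $\ge 2$ are merged across gaps up to 1 kb. Defaults mirror the
conventional stringent threshold (`-p 0.00001`) and give, on null genomes,
a mean false-positive count well below the Bonferroni-style bound
$p \cdot n_\text{bins}$ (checked over repeated simulations in the test
suite). γH2AX-against-H3 calling is the same operation with different
input tracks; no separate code path exists.

## Directionality

Peak membership in a gene is decided by the peak **center** (the summit when
available), giving every peak exactly one class; any-overlap membership is
available via `membership = "overlap"`. When a center falls inside two
overlapping transcribed genes, the gene with the higher expression wins —
the dominant transcription unit defines the collision context; the event is
messaged so it can be audited. Fork directions are an explicit input (in
practice imported from replication-timing work, or the synthetic truth);
the package does not infer them from timing gradients.

## Overlap statistics

`closest_distance()` reports 0 exactly when intervals intersect; otherwise
the gap in bp between nearest edges, with *adjacent* half-open intervals
reported as 1. The special case keeps "distance 0" synonymous with
"overlap", which the downstream Boolean statistic depends on. Queries on
chromosomes without features get `Inf` and are excluded from overlap
fractions rather than scored as non-overlaps — scoring them would penalise
unshared contigs.

`permutation_test()` computes $t^* = \bar d_A - \bar d_B$, the difference
of overlap fractions, and resamples group labels over the pooled Boolean
vector. For indicator data the label-permutation distribution of the
group-A overlap count is exactly hypergeometric, so the null is sampled
directly from it — equivalent to permuting labels but orders of magnitude
faster, and verified against exhaustive enumeration of label splits for
small groups in the tests. Because the published procedure is ambiguous
between permutation and bootstrap ("bootstrap permutation"), a
with-replacement mode (`method = "bootstrap"`) is also provided; the
without-replacement permutation is the default. The default sidedness is
two-sided (the alternative is an inequality); a one-sided flag exists for
directional questions. Multiple tests are adjusted with
Benjamini–Yekutieli via `stats::p.adjust`, the step-up rule inflated by
$c(m)=\sum_{i\le m} 1/i$, valid under arbitrary dependence between tests
sharing the same breakpoint table.

`genome_shuffle_test()` relocates each query uniformly within its own
chromosome (length-preserving) and counts queries touching any feature;
`shuffle_within_genes()` relocates peaks uniformly within their host gene,
leaving orphan peaks in place and flagged. Both preserve interval counts
and lengths exactly in every iteration.

## Metagene and the density-decline estimator

Profiles sample the track at bin-center resolution around anchor centers
(strand-aware on request) or across gene bodies rescaled to a fixed number
of positions; means are taken over contributing anchors, so truncated
windows at chromosome ends simply contribute fewer anchors per position,
and the profile operator is linear in the track.

The replication-speed proxy compares a TSS-anchored metagene over
transcribed genes longer than 100 kb between (i) a 10-kb upstream baseline
and (ii) the minimum of the profile over the first 100 kb of gene body
after a 5-kb moving-average smooth. The baseline uses the upstream flank
rather than the TSS bin itself because TSS-proximal bins carry origin- and
promoter-associated signal; upstream signal is empirically independent of
gene length, which is what makes it a usable reference. Smoothing before
taking the minimum prevents single-bin Poisson minima from inflating the
reduction; the residual effects are a small smoothing bias on a V-shaped
profile (≈ 0.2 percentage points at the default bandwidth) and a ~1-point
upward noise bias from taking a minimum over a noisy curve — both inside
the ±2-point recovery band the tests enforce. Windowed correlation uses
1-kb windows and keeps those with ≥ 10 reads in both tracks, then reports
Pearson's r.

## Elongation rates

`recovery_time()` finds the first time a primer's pre-mRNA level returns to
within 10% of the control plateau, linearly interpolating between the
bracketing samples; a snap-to-grid mode reproduces the coarser procedure of
reading raw 10-min samples. Segment rates divide inter-primer distance by
the difference of recovery times; non-increasing or tied times flag the
segment undefined, and the gene rate is the mean of defined segments.
Treatment effects are percent reductions versus the control's mean rate.
Rates are invariant to uniform rescaling of levels (the reference-gene
normalisation cancels). A hard limitation worth stating: with primers at
1/15/40/60/80 kb sampled every 10 min, a segment is only resolvable when
its true traversal time exceeds roughly two sampling intervals; at
4 kb/min the 20-kb segments take 5 min and the assay cannot measure them.
The tests assert recovery only where the design can resolve it, and the
percent-reduction readout (a ratio) is much more robust than the absolute
rates.

## The synthetic-data generator

The generator defines the study conditions for every validation: a
2 × 10 Mb genome in 500-bp bins, 150 non-overlapping genes (25% drawn from
a long, >100 kb component; log-normal expression with 80% of genes
transcribed), a replication-timing program of 500-kb domains assigned to
the five S-phase timepoints with early-skewed weights, mean depth 30
reads/bin, and 80 planted hotspots of 2 kb, occupancy 0.5 and 10-fold
amplitude. Occupancy is not quantified experimentally anywhere we know of,
so it is a free parameter swept in tests; 0.5 at amplitude 10 gives
hotspot bins a Poisson mean of $30(1 + 0.5 \cdot 9) = 165$, a
mid-strength signal rather than a trivially detectable one. The sample
track is Poisson(depth) genome-wide with hotspot bins elevated in their
own timepoint only; this makes the occupancy-0 case *exactly* exchangeable
with the input, which is the null the false-positive tests rely on, while
the timing program still controls where hotspots and genes sit.
Breakpoint-enriched hotspots are drawn from the earliest S timepoint,
matching the observation that early-replicating stalling sites carry the
instability signal.

The ChIP decline is planted as a linear fall from baseline at the TSS to
baseline·(1 − d/100) at 75 kb followed by a linear half-slope recovery
capped halfway back to baseline. The partial recovery (rather than a flat
tail) is what the underlying profile shape shows and is also what makes
"minimum position" a well-posed estimand: over a flat tail plus noise the
argmin would be uniform over the tail, and no estimator could localise it.

The DRB-release timecourse models the population-level pre-mRNA level at a
primer as a linear rise over 20 min (two sampling intervals — cells lose a
little synchrony after release) ending at the polymerase arrival time
(primer distance / rate), sampled every 10 min from release. With this
shape the interpolated crossing times differ from arrival by a nearly
constant offset that cancels in segment differences, so planted rates come
back to within a few percent where the sampling can resolve them.
Measurement noise defaults to 0 (the recovery analysis is deterministic);
a `noise_sd` knob exists for robustness experiments.

What the generator does **not** emulate: fragment-length and GC biases,
mappability, diploidy, replication-timing heterogeneity between cells,
copy-number structure in rearrangement tables, and genuine sequence
composition (no genome sequence is generated — composition operations are
validated on explicit sequences). Passing tests therefore demonstrate the
estimators' correctness under the stated signal model, not robustness to
every artefact of real sequencing data.

## Problem sizes and determinism

Validation suites run at the generator's native scale: 20 simulated genomes
for detection and decline recovery, 500 null replicates at B = 1,000 for
the permutation test's size, 1,000-iteration shuffles, and 200-run
calibration checks — sizes chosen so the whole suite completes in a couple
of minutes while keeping Monte-Carlo error well inside the asserted bands.
All generators consume streams seeded deterministically from the
configuration seed plus the stage name, so identical configurations yield
bit-identical outputs; `run_pipeline()` extends the same scheme to the
analysis stages and records seeds and parameters in its manifest.

## Known limitations

The caller does not model fragment shifts, duplicate reads or
copy-number-variable backgrounds. Directionality requires an external fork
direction map and misclassifies peaks straddling gene boundaries in the
rare case where summit and center disagree with the hosting gene. The
density-decline figure is one documented realisation of a schematically
described measurement (endpoint-vs-baseline on a smoothed metagene);
alternative realisations (fitted slopes) would differ at the
percentage-point level. The breakpoint permutation test treats both
breakpoints of a rearrangement as independent events, which overstates the
effective sample size when both ends of the same rearrangement fall in the
same query set.
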