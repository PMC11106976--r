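# forkstall

Detection and characterisation of **transient replication fork
stalling/pausing hotspots** from multi-timepoint BrdU-Seq, and of their
relationship to transcription and genome instability.

## The problem

In synchronised human cells pulsed with BrdU at successive S-phase
timepoints, immunoprecipitated nascent-DNA coverage is flat over the regions
replicated during each pulse — except where replication forks pause in a
fraction of cells. Those sites accumulate an over-representation of labelled
reads: a BrdU peak. Such peaks are *transient*: a hotspot is elevated in its
own timepoint and decays by the next, so it is only visible when replication
is profiled at multiple points through S phase. `forkstall` is for genomics
analysts who want to call these hotspots, ask whether they sit in transcribed
genes co-directionally or head-on with the replication fork, test whether
they coincide with structural-rearrangement breakpoints and fragile sites,
and quantify two companion readouts: the decline of replication-factor ChIP
density along long transcribed genes (a relative replication-speed proxy)
and RNAPII elongation rates from DRB-release pre-mRNA recovery timecourses.

## The statistics at the core

* **Peak calling.** Bins of the sample track are tested against a Poisson
  null with local rate λ = max(input mean over 1 kb, over 10 kb, genome
  background); bins with upper-tail *p* < 10⁻⁵ and fold ≥ 2 are merged into
  peaks.
* **Overlap permutation test.** For query sets *A* and *B* with
  nearest-breakpoint distance vectors **d**_A, **d**_B (distance 0 ⇔
  overlap), the statistic is
  *t\** = d̄_A − d̄_B, where d̄_X is the mean of the Boolean vector
  [**d**_X = 0]. The null is built by resampling group labels over the
  pooled Boolean vector (≥ 10,000 resamples); p-values across tests receive
  **Benjamini–Yekutieli** correction, the step-up FDR adjustment with the
  harmonic inflation c(m) = Σ 1/i that is valid under arbitrary dependence.
* **Genome-shuffle test.** Length-preserving uniform relocation of query
  intervals, with the empirical enrichment p-value
  (1 + #{null ≥ observed}) / (iterations + 1).
* **Density decline.** Over genes > 100 kb, the TSS-anchored metagene is
  compared between an upstream baseline and its smoothed minimum within the
  first 100 kb: percent reduction = 100·(baseline − minimum)/baseline.
* **Elongation rates.** Per primer, the time for pre-mRNA to return to the
  control plateau after DRB release; segment rate = Δdistance/Δtime,
  averaged over the gene; treatment effect = 100·(control − treated)/control.

Every estimator is validated against a synthetic-data generator
(`sim_config()`, `simulate_genome()`, `simulate_brdu_timecourse()`, …) that
plants hotspots, collision structure, ChIP declines, breakpoint enrichment
and elongation rates, and emits ground-truth tables.

## Worked example

```r
library(forkstall)
bundle <- forkstall_demo(seed = 7)   # simulate + run every stage

print(bundle$breakpoint_test)
#> overlap permutation test (permutation, two.sided)
#>   d_bar_A = 0.8000 (n=25), d_bar_B = 0.0364 (n=55)
#>   t* = 0.7636, p = 9.999e-05 (B = 10000)

print(bundle$decline)
#> density decline over 31 genes: 18.7% reduction, minimum 76 kb downstream of TSS

print(bundle$elongation)
#> elongation rate estimates (kb/min)
#>   alphaAm    mean 1.41  (31.8% vs DMSO)
#>   DMSO       mean 2.06
#>   DRB        mean 0.93  (54.8% vs DMSO)

round(bundle$transience, 2)
#>             Early S Early/Mid S Mid S Mid/Late S Late S/G2
#> Early S        4.57        1.04  1.01       1.01      1.01
#> Early/Mid S    1.02        4.48  1.09       1.00      1.02
#> Mid S          1.06        1.05  4.38       1.04      1.03
#> Mid/Late S     0.99        1.05  1.04       4.20      1.00
#> Late S/G2      0.99        1.04  1.06       1.03      4.24
```

Reading the output: 80% of first-timepoint peaks overlap a breakpoint window
versus 3.6% of later-timepoint peaks (t\* = 0.76, the smallest p attainable
at B = 10,000) — the planted early-S breakpoint enrichment is recovered. The
transience matrix shows each timepoint's peak set at ~4–5× input-normalised
signal in its own timepoint, decaying to ~1× everywhere else. The density
decline and elongation estimates recover the planted 17.2% / 75 kb decline
and the planted 52%/33% rate reductions up to sampling quantisation.

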