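# tempoBMT

Benchmark-time modeling of temporal transcriptomics time courses.

## What it is for

Targeted bulk transcriptomics (TempO-Seq-style probe panels) can profile a
compound exposure at many *time points* instead of many concentrations.
tempoBMT analyzes such designs end to end for cell-stress toxicology: which
genes respond, which stress-response pathways (Nrf2 oxidative stress,
unfolded protein response, metal stress) are over-represented, and — the
centrepiece — *when* each gene's response starts. For the last question it
repurposes benchmark-dose (BMD) curve modeling to the time axis: the
**benchmark time (BMT)** of a gene is the earliest time at which its fitted
time-response curve departs from baseline by a benchmark response (BMR).
Ranking genes and pathways by BMT separates proximal transcriptional events
from downstream ripples, e.g. metal-stress genes switching on hours before
the unfolded protein response.

The package is written for the paper-scale design: 9 exposure times between
1 and 24 h, 3 biological replicates, matched vehicle controls at every time
point (27 treated + 27 control samples per compound), and a ~3,565-probe
panel.

## The method in brief

For each compound:

1. **Filter & normalize** — probes with read-count row sum < 100 across the
   compound's treated + control samples are removed; samples are scaled by
   median-of-ratios size factors.
2. **Per-time-point differential expression** — negative-binomial Wald
   tests of treated vs time-matched control at fixed per-probe dispersion;
   a probe is a DEG at BH-adjusted p < 0.01 and fold change > |2|.
3. **Pathway over-representation** — hypergeometric upper-tail test of the
   DEG gene list at the peak-DEG time point against a GMT collection, panel
   as background; significant at overlap ≥ 5, p < 0.01, FDR q < 0.05.
4. **Benchmark times** — probes passing a Williams-type trend prefilter
   (permutation p < 0.05, max |log2FC| > 1) are fit with ten parametric
   families (Linear, Poly2–4, Power, Hill, Exp2–5); the lowest-AIC fit is
   inverted at the BMR (default 1.349 × the t = 0 anchor SD); bounds come
   from a parametric bootstrap that re-runs model selection per replicate;
   results are retained when the BMT lies in 0.1–24 h, BMTU/BMTL < 40 and
   the goodness-of-fit p > 0.1. Summaries: BMT accumulation curves,
   earliest-response genes, and a weighted 5-parameter-logistic predicted
   log2FC at the BMT.

A first-class synthetic-data module (`simulationConfig`,
`simulateExperiment`) generates negative-binomial count experiments with
planted, analytically characterized responders, so every stage is testable
against ground truth without any external data.

## A worked example

Simulate a two-compound screen (an early-acting metalloid-like archetype and
an inert negative control) on a 400-probe panel and run the full pipeline
against the planted truth:

```r
library(tempoBMT)
cfg <- simulationConfig(nProbes = 400L, pathways = defaultPathways(10L),
                        compounds = defaultArchetypes()[c(1, 5)], seed = 7L)
res <- simulateAndRun(cfg, nPerm = 500L, nBoot = 100L)
res$metrics
#>          compound degSensitivityPeak degFdrPeak             topOraSet
#> 1 metalloid_early                0.8     0.0476          metal_stress
#> 2   inert_control                 NA     0.0000 Nrf2_oxidative_stress
#>   plantedOraRank nRetainedBmt bmtMedianRelError earliestGeneOnsetCor
#> 1              1           22             0.238                0.587
#> 2             NA            4                NA                   NA
```

Read: at its peak-DEG time point the active compound recovers 80% of the
planted responders with ~5% false discoveries, its planted pathway ranks
first in the ORA, 22 probes survive the BMT retention filters with a median
relative BMT error of 0.24 against the analytic truth, and the
earliest-gene ordering correlates positively with the planted onset order.
The inert control plants nothing, so truth-based columns are NA and only a
handful of noise probes are retained.

Stage detail for the active compound:

```r
r <- res$report$compounds$metalloid_early
r$nSignificant
#>  1  2  4  6  8 12 16 20 24
#>  0  4 18 20 21 19 21 21 20
r$peakTime
#> [1] 8
head(r$ora[["8"]][, c("set", "k", "m", "n", "N", "p", "q", "significant")], 3)
#>                     set k  m  n   N        p        q significant
#> 3          metal_stress 9 10 21 400 4.33e-12 8.66e-12        TRUE
#> 1 Nrf2_oxidative_stress 7 10 21 400 4.11e-08 4.11e-08        TRUE
#> 2                   UPR 4  10 21 400 9.70e-04       NA       FALSE
```

The UPR row shows the overlap gate at work: overlap 4 < 5, so the set is
excluded from the FDR family (q = NA) and cannot be significant regardless
of its raw p. `r$bmt` holds the per-probe BMT table, `r$accumulation` the
cumulative BMT curve, and `r$earliestGenes` the first-significant-time gene
ranking (here the metallothionein genes MT1M/MT1E lead at 2 h).

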