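# vtaSst

Electrophysiological subtyping of somatostatin (Sst) neurons in the
mouse ventral tegmental area (VTA), as an R package.

Sst-expressing neurons of the VTA are a heterogeneous population
embedded in the midbrain dopamine system. Whole-cell current-clamp
recordings (800 ms steps, −100 → +600 pA in 10 pA increments, 10 kHz)
separate them into three subtypes: **ADP** cells with a prominent
afterdepolarization after each spike, **HFF** cells firing at the
highest maximal rates, and **Delayed** cells that fire only after a
long delay even at strong depolarization. `vtaSst` implements the
full quantitative pipeline around that result, for electrophysiologists
and computational neuroscientists who want to apply or scrutinize it:

* **Feature extraction** — 25 passive and active membrane features per
  cell (resting potential, input resistance, sag, membrane time
  constant, rheobase, spike threshold at the first sample where
  dV/dt > 10 mV/ms, amplitude, half-width, AHP, decay, ADP bump,
  latencies, maximal firing rates, adaptation ratio
  `fmax_ss / fmax_init`, spike counts, interval CV).
* **Subtyping** — log transform of count/latency features, 5×IQR
  outlier removal, min-max scaling, PCA order selected by five-fold
  cross-validated BIC over probabilistic-PCA models (k = 1…9), then a
  full-covariance Gaussian mixture with K = 1…7 selected the same way,
  and hallmark-based cluster naming.
* **Optogenetic circuit maps** — optical footprints and IPSC input
  maps on 32 × 32 / 16 µm photostimulation grids with the ≥ 2/3-trials
  rule, pixel-area arithmetic (256 µm² per pixel), connected-cluster
  counts, convergence summaries, and Nernst reversal-potential /
  solution-chloride utilities.
* **Patch-seq QC and normalization** — strict 75,500-read and
  50%-alignment floors, the depth-correlated-gene PC1 + 1 normalization
  factor, bootstrap mapping of cells onto reference clusters, and
  Sst-anchored cross-dataset comparison.
* **Anatomy** — section-count scaling to whole-VTA estimates, marker
  ratios, neurotransmitter co-expression classes, rostro-caudal
  profiles.
* **Synthetic data** — generators for every input class (trace ladders
  with closed-form ground truth, photostimulation sessions, Patch-seq
  count matrices) parameterized by the published subtype table, so the
  entire pipeline is testable without any external download.

## Worked example

```r
library(vtaSst)

## a synthetic cohort at the published sizes (215 ADP / 92 HFF / 85 Delayed)
fm <- synthFeatureTable(seed = 1)
cc <- clusterCells(fm, seed = 1)
model <- nameClusters(cc$model, cc$retained)
model
#> ClusterModel: 2 PCs, K = 3 components, 369 cells
#>   clusters: ADP, HFF, Delayed

summ <- clusterSummary(cc$retained, model@clusterNames[clusterLabels(model)])
summ$n
#>     ADP Delayed     HFF
#>     212      70      87
round(summ$mean[, c("adp_amplitude", "fmax_init", "first_spike_latency_sat")], 1)
#>         adp_amplitude fmax_init first_spike_latency_sat
#> ADP              14.2     106.1                    50.8
#> Delayed           0.0     123.3                   314.7
#> HFF               0.0     129.6                    15.0
round(summ$grandMean["input_resistance"])
#> 846
```

Cross-validated BIC selects two principal components and three mixture
components; 23 cells fall to the 5×IQR outlier rule, and the remaining
369 cells split into clusters whose hallmark features match their
generating subtypes (the ADP cluster carries the ~14 mV
afterdepolarization, the Delayed cluster the ~300 ms latency). On a
single noiseless rendered ADP cell the extractor returns the
afterdepolarization exactly:

```r
r <- synthTraceLadder(defaultSubtypeSpecs()$ADP, seed = 1, noiseSd = 0)
round(extractFeatures(r$ladder)["adp_amplitude"], 1)
#> 13.8
nernstPotential(-1, solutionChloride(c(KCl = 140, NaCl = 4, CaCl2 = 0.5)),
                    solutionChloride(c(NaCl = 126, KCl = 1.6,
                                       MgCl2 = 1.2, CaCl2 = 2.5)), 24)
#> 1.829...   # mV; the chloride reversal under the recording solutions
```

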