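---
title: "Methods: electrophysiological subtyping of VTA somatostatin neurons"
author: "vtaSst package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: electrophysiological subtyping of VTA somatostatin neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtaSst)
```

# Scope

`vtaSst` implements the quantitative analysis behind the identification
of three somatostatin (Sst) neuron subtypes in the mouse ventral
tegmental area (VTA): current-clamp feature extraction, cross-validated
model selection for PCA order and mixture size, Gaussian-mixture
subtyping, optogenetic circuit-map analysis, Patch-seq quality control
and normalization, and anatomical count scaling. Because the original
raw recordings are external, the package ships a synthetic-data module
that emulates every input class with closed-form ground truth, so the
whole pipeline is testable end to end.

# Current-clamp protocol and feature extraction

A `SweepLadder` holds one cell's responses to 800 ms square current
steps from −100 to +600 pA in 10 pA increments, sampled at 10 kHz
(`dt = 0.1` ms). Cells are excluded when the mean pre-step baseline
(resting membrane potential, RMP) exceeds −50 mV or when the per-sweep
baseline SD exceeds 6 mV; both comparisons are strict. The baseline is
measured over the pre-step segment of each sweep, the only window that
is guaranteed current-free; whether the original analysis used pre-step
segments or inter-sweep holding periods is not recoverable, so this is
a documented package choice.

The 25-feature roster (`featureRoster()`) comprises five passive
features, ten from the rheobase sweep (the lowest step that elicits a
spike) and ten from the saturated sweep (the step with the most
spikes, ties resolved toward the lowest current). Definitions follow
the field's conventions:

* **Spike threshold**: the first sample at which the voltage slope
  exceeds 10 mV/ms. The slope is computed by central differences after
  3-point moving-average smoothing, because raw differencing at 10 kHz
  is noise-dominated. Candidate spikes rising less than 20 mV above
  threshold are rejected so afterdepolarization bumps are not counted
  twice; the paper states no amplitude floor, so 20 mV is a package
  default. The spike peak is the first qualifying local maximum after
  the crossing — a bounded window-global maximum can skip to the next
  spike when interspike intervals are short.
* **Half-width**: width at threshold + amplitude/2, crossings located
  by linear interpolation.
* **AHP amplitude**: threshold minus the most negative voltage after
  the peak (bounded 50 ms lookahead so post-step repolarization is
  never mistaken for an afterhyperpolarization); **decay time** is the
  peak-to-trough interval.
* **ADP (afterdepolarization)**: searched from the AHP trough to the
  next spike threshold, the trough + 100 ms, or the step end, whichever
  comes first. A bump registers only as an interior local maximum that
  rises at least 0.5 mV above the trough *and* declines again by at
  least 0.5 mV before the window ends; the prominence condition keeps a
  monotone recovery toward the next spike from masquerading as a bump
  under noise. Both ADP fields are 0 when no bump is found.
* **Rates**: the initial maximal frequency is the inverse of the
  shortest of the first two peak-to-peak intervals; the steady-state
  maximal frequency is the inverse of the mean of the last four
  intervals (of all intervals when fewer than four exist; missing with
  fewer than two spikes); the adaptation ratio is their quotient.
* **Passive**: input resistance is the least-squares slope of
  steady-state voltage (last 50 ms of the step) against current over
  spike-free sweeps; sag is the ratio of the last-50 ms mean to the
  most negative voltage of the −100 pA sweep, as absolute voltages (a
  deflection-relative variant sits behind `sagMode = "deflection"`);
  the membrane time constant comes from a single-exponential fit of the
  −100 pA onset over 2–200 ms (the first 2 ms are skipped as capacitive
  transient), via Levenberg–Marquardt least squares, flagged `NA` when
  the fit does not converge.

# Preprocessing and subtype clustering

Count-like features (spike counts, ADP latency) are transformed as
log(x + 1) and strictly positive latencies as log(x). Cells with any
transformed value farther than 5 interquartile ranges from the feature
median are discarded in a single pass, on transformed but unscaled
values; surviving columns are min-max scaled to [0, 1].

"BIC estimated with fivefold cross-validation" is ambiguous, since the
classical BIC needs no held-out data. The package's reading: for each
candidate, fit on the training folds, evaluate the held-out
log-likelihood, penalize with the full model's parameter count and the
held-out sample size, and average over folds. For the PCA order the
candidate models are probabilistic PCA (closed-form maximum-likelihood
solution from the training covariance eigendecomposition) with k = 1–9;
for the mixture size, full-covariance Gaussian mixtures with K = 1–7
fitted by `mclust` (model "VVV"). `mclust`'s deterministic model-based
hierarchical agglomeration provides the initialization; this replaces
random multi-start initialization because it is reproducible given the
fold assignment alone. Both selection curves are verified in the test
suite against independent exhaustive enumerations using a directly
coded Gaussian likelihood.

Cluster naming uses one hallmark per subtype: ADP amplitude (ADP),
initial maximal rate (HFF) and saturated-sweep first-spike latency
(Delayed). Cluster means of the hallmarks are standardized and names
assigned by the bijective matching with the largest summed evidence.
A greedy "argmax per hallmark" rule was rejected: with population SDs
reconstructed as SEM × sqrt(n), zero-truncation inflates the Delayed
subtype's firing-rate draws (mean 46, SD ≈ 138 Hz) to a truncated mean
near 128 Hz, rivaling the HFF mean, so greedy naming ties on
realistic cohorts. New cells can be labelled under a frozen model
(stored scaling, loadings and mixture responsibilities) or by a joint
refit of the pooled cohort.

# Optogenetic circuit maps

Photostimulation sessions are 32 × 32 scans at 16 µm pitch (510 µm
field, 0.26 mm²; single-pixel area 256 µm²), three trials per pixel.
A pixel joins the optical footprint when ≥ 2/3 of trials evoked an
action potential; an input-map pixel is active when an IPSC event was
evoked in ≥ 2/3 of trials, its amplitude the mean over event trials and
the map normalized by the maximum pixel. The event-detection threshold
is unstated in the source; the package uses the larger of a 5 pA floor
and 3× the baseline noise SD, conservative against the smallest
reported evoked IPSC of 8 pA. Discrete input clusters are counted with
4-connectivity; pixel centers sit at (i + 0.5)·pitch, row-major, a
convention the package documents because none is stated. Convergence
summaries report medians and IQRs of areas and the ratio of medians
only — inferring the number of presynaptic cells is out of scope by
design. The Nernst utility computes E = (RT/zF)·ln([out]/[in]); with
the stated internal (140 KCl + 4 NaCl + 0.5 CaCl₂ → 145 mM Cl⁻) and
bath (126 NaCl + 1.6 KCl + 1.2 MgCl₂ + 2.5 CaCl₂ → 135 mM Cl⁻)
solutions at 24 °C it returns +1.8 mV.

# Patch-seq quality control and normalization

Cells with fewer than 75,500 total reads are discarded first, then
cells with alignment below 50%; both floors are strict, so a cell at
the boundary is kept. The normalizing gene set intersects genes
significantly correlated with the reference's per-cell molecular count
(Pearson, Benjamini–Hochberg at α = 0.05 — the source names neither
test nor correction, so these defaults are documented here) with genes
detected in every Patch-seq cell. Expression over that set is reduced
to PC1; the sign is fixed by positive correlation with per-cell total
counts, and the scores are rescaled to half-unit maximum amplitude
before the +1 offset, giving factors in (0.5, 1.5]. The rescaling is a
package decision: raw PC1 scores of count data are O(100), so "+1"
cannot keep them positive, yet the offset's intent — strictly positive,
depth-monotone factors near 1 — is preserved; a guard still hard-errors
on any nonpositive factor.

Bootstrap mapping standardizes expression per gene with the reference
mean and SD, scores each cell against every cluster centroid by
Pearson correlation, and compares the observed score with scores under
`nBoot` random permutations of gene identities (p = fraction of null ≥
observed; assignments at p < 0.05, multiple allowed). A
label-permutation null (recomputing centroids from shuffled reference
labels) is retained behind `null = "labels"` but is not the default:
permuted-label centroids collapse onto the grand-mean profile, making
that null far too narrow — measured false-assignment rates near 0.4 at
α = 0.05 versus 0.03 for the gene-permutation null, which the test
suite verifies stays below 0.07.

# Anatomical counts

Whole-structure totals scale a sampled count by counted / percent ×
100 (40% for the immunostained series, 9% for the in-situ series; the
fractions are user inputs because their derivation from section
geometry is not fully recoverable). Co-expression of the GABA,
glutamate and dopamine transporter markers collapses to the categories
GABA, Glu, GABA+Glu, DA and "other" (all remaining combinations,
including triple positives), matching the reporting granularity of the
source figure; the full combination table is also returned.
Cross-subtype "grand means" are unweighted means of cluster means —
this matches the published arithmetic (849 MΩ, 92 mV, 1.1 ms,
−67.5 mV), which is inconsistent with n-weighting; an n-weighted
option exists behind a flag. Group comparisons use one-way ANOVA with
Tukey HSD; the Tukey–Kramer form applies automatically since cluster
sizes differ.

# The synthetic-data module

`defaultSubtypeSpecs()` encodes the three subtypes with population
means from the published summary table (cohort sizes 215/92/85) and
SDs reconstructed as SEM × sqrt(n). Five roster features have no
published summary: the membrane time constant (defaults 15/12/20 ms
for ADP/HFF/Delayed — within the range implied by the cells' input
resistance and capacitance), ADP latency (20 ms, ADP only),
saturated-sweep amplitude and AHP (rheobase values minus 5 and 2 mV),
and the interspike-interval CV (0.30/0.25/0.15). These were fixed once
as field-typical values and are not tuned.

`synthFeatureTable()` draws each feature independently from truncated
Gaussians (latencies, rates and widths at 0; sag at 1); ADP fields are
forced to 0 for non-ADP subtypes, spike counts are rounded to whole
spikes with the saturated count kept at or above the rheobase count,
and the adaptation ratio is recomputed as fmax_ss/fmax_init so the
defining identity holds row-wise. Inter-feature correlation is not
emulated — the source reports none — which makes the clustering task
somewhat easier than real data; passing recovery tests therefore
demonstrates correctness of the pipeline, not a guarantee about noisy
biological cohorts.

`synthTraceLadder()` renders membrane-potential traces from smooth
closed-form templates rather than a conductance-based model, so every
extracted feature has an exact target: a quadratic approach whose slope
hits 10 mV/ms exactly at the scheduled threshold, a linear rise and
biphasic fall with knots snapped to the sample grid (peak, trough and
half-width therefore land exactly), an optional Gaussian ADP bump
riding on a plateau held 1 mV above the trough (keeping the trough a
distinct minimum under noise), and interspike intervals following an
exponential-approach schedule solved so the first interval and the
mean of the last four match the target rates. Spike trains that would
overflow the 800 ms step are truncated with a warning. Additive
Gaussian noise (default 0.2 mV) is the only stochastic element; it
emulates recording noise but not channel kinetics, electrode artifacts
or seal instability. The generator emits the ground-truth feature
vector implied by the realized grid-aligned schedule.

`synthPhotostimSession()` places disc-shaped sources on the scan grid
(per-trial success probability 0.95 inside, 0.01 outside) with
connected sources contributing IPSC amplitudes drawn from the reported
8–218 pA range. `synthPatchseq()` draws cluster-structured
negative-binomial counts; a designated subset of genes loads on a
latent depth factor (and is ubiquitously detected), making the
normalizing gene set recoverable, and a configurable number of cells is
pushed below each QC floor so the 61-of-69 margin is reproduced by
construction.

# Numerical choices and problem sizes

Tolerances used in the test suite: noiseless trace recovery within 2%
or one sample (trough-referenced timing within one sample); noisy
(0.2 mV) recovery within 6% relative, with absolute slacks for
trough-timed quantities whose location degrades gracefully in noise.
Tests render ladders on a 20 pA current grid (invariants are unchanged;
rendering cost drops four-fold) and use cross-validation exactly as the
defaults prescribe. The cluster-recovery check runs the full
392-cell cohort over 10 seeds and requires K = 3 with adjusted Rand
index ≥ 0.9 and mixture weights within 0.05 of 215/92/85 in the
majority; the bootstrap calibration check uses 200 permuted cells and
400 permutations. These sizes were chosen as the smallest that make the
statistical claims meaningful.

Degenerate inputs: constant feature columns are dropped with a warning
before scaling; a zero interquartile range disables the outlier rule
for that feature; a degenerate covariance in probabilistic PCA is
floored at 1e−9; mixture fits that fail on a fold are excluded from
that fold's average; clusters with zero-variance centroids are skipped
in bootstrap mapping with a warning.

# Known limitations

* HDF5 and Axon Binary recordings must be exported to the CSV long
  dialect first; the package bundles no binary readers.
* The synthetic subtypes are caricatures: independent features, smooth
  template spikes, linear pre-spike ramps. They validate the pipeline's
  measurement and selection machinery, not its behavior on pathological
  recordings.
* Reference-atlas clustering is consumed as given labels; the package
  does not re-derive them.
* Published cluster sizes (215/92/85) depend on the original
  intermediate data and exact fold/initialization seeds, which are
  external; the package reproduces the structure (three clusters,
  comparable weights), not the literal partition.
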