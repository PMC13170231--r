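---
title: "neuroXmap: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{neuroXmap: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroXmap)
```

neuroXmap implements an imaging-transcriptomics workflow for systemic
autoimmune disease (its motivating application is thyroid eye disease):
spontaneous-activity mapping from resting-state fMRI, atlas-constrained
regional transcriptome construction from donor microarrays, gene-wise
spatial correlation, gene-set / cell-type scoring, peripheral-blood
differential expression and immune-signature scoring, and brain–immune
correlation. This vignette records the models behind each stage, the
tunable parameters with their defaults, the numerical choices, what the
synthetic-data generators emulate, and the limitations of both.

## 1. ALFF and its standardizations

Each voxel's time series (dummy volumes already discarded upstream; the
container requires at least 64 retained timepoints) is linearly detrended
and transformed with the FFT. With $N$ timepoints at repetition time $TR$,
the one-sided amplitude spectrum is $a_k = (2/N)\,|X_k|$ at frequencies
$f_k = k/(N\,TR)$, and

$$\mathrm{ALFF} = \operatorname{mean}\{a_k : f_\text{low} \le f_k \le f_\text{high}\},$$

with the conventional band 0.01–0.08 Hz. We use the band *mean* rather than
the band sum so the statistic does not change when a different $N$ places
more bins in the band; for a noise-free sinusoid of amplitude $A$ on one of
$m$ in-band bins, ALFF is exactly $A/m$. One numerical subtlety: the linear
trend regressor is not exactly orthogonal to a finite sinusoid, so
detrending perturbs that closed form slightly; `computeALFF(detrend =
FALSE)` exists for analytic checks, and signals orthogonal to $\{1, t\}$
(e.g. opposed cosine pairs) preserve the closed form to machine precision
with detrending on. The tests exercise both routes.

Two standardizations are provided. `global-mean-divide` (mALFF) divides by
the in-mask mean, making the in-mask mean exactly 1. `z` subtracts the
in-mask mean and divides by the in-mask SD. The literature often labels the
second step "Fisher's z-transformation"; the arc-tangent transform is
undefined for mALFF values ≥ 1 (half the brain, by construction), so the
literal reading is impossible on real maps and ordinary z-standardization
is what is implemented — both modes are exposed and `z` is the default
normalization after mALFF.

## 2. Voxel statistics and cluster-level inference

Covariate designs give voxel-wise Pearson r with two-tailed p on $n-2$ df;
two-group designs give the equal-variance two-sample t on $n_1+n_2-2$ df
(the convention of standard neuroimaging software). Voxels with zero
variance across subjects are recorded missing and excluded from cluster
formation.

Smoothness is estimated from per-subject residual maps: after unit-variance
normalization, the variance $v_d$ of spatial first differences along each
axis gives the lag-one autocorrelation $\rho = 1 - v_d/2$, and for a
Gaussian autocorrelation model $\mathrm{FWHM}_{vox} =
\sqrt{-2\ln 2/\ln\rho}$, floored at one voxel (white noise attains the
floor). The estimator recovers known kernel widths within 20% for kernels
of ≥ 2 voxels FWHM and orders anisotropic axes correctly.

Cluster correction converts the statistic field to standard-normal
equivalents through its CDF, thresholds at the voxel-level p (default
0.005 for correlation maps, 0.001 for the group contrast), forms clusters
by face adjacency (6-connectivity; 18/26 available), and assigns each
cluster the random-field corrected p

$$p = 1 - \exp\!\big(-E[m]\; e^{-\beta k^{2/3}}\big),
\qquad \beta = \left(\Gamma(5/2)\,E[m]/E[N]\right)^{2/3},$$

where $E[m]$ is the expected supra-threshold cluster count from the
expected Euler characteristic at resel volume $V/\prod \mathrm{FWHM}$ and
$E[N]$ the expected supra-threshold voxel count. Two-tailed testing is run
as two one-sided analyses, one per sign, each at the stated voxel p. On 500
simulated smooth Gaussian null fields (24³ voxels, FWHM 2 voxels) the
family-wise error at nominal cluster p 0.05 is ≈ 0.03 — the calibration the
acceptance suite re-measures. A permutation backend (max-cluster-extent
null over design relabellings) serves as the assumption-free oracle; on
simulated datasets its retain/reject decisions agree with the random-field
backend on > 95% of formed clusters.

ROIs follow the minimum-spatial-extent rule: a parcel becomes an ROI when
at least `min_voxels = 6` of its voxels lie in retained clusters. The
reference analysis this package generalizes reports 19 such ROIs on its
patient cohort; that number depends on unavailable clinical data and is a
documented use case, not a desk-reproducible quantity.

## 3. Regional expression from donor microarrays

Probes are dropped when they lack a valid gene id or fall below background
in ≥ 50% of samples (inclusive), pooled across donors. No background
definition is universal; the default threshold is the bundle-wide median
intensity, overridable per bundle — the synthetic bundles record an
explicit threshold that exactly separates their bimodal design. Samples
are assigned to the parcel containing them, or to the nearest labelled
voxel within 2 mm subject to hemisphere agreement (sign of x; midline
parcels match both). Unassigned samples are excluded and counted.

Within each donor and gene, values are robust-sigmoid normalized,
$x' = 1/(1+\exp(-(x-\mathrm{med})/(\mathrm{IQR}/1.35)))$, then min–max
rescaled to $[0,1]$; if the IQR is zero the SD substitutes, and if both are
zero the gene is dropped for that donor. Differential stability — the mean
over donor pairs of the Pearson correlation between regional profiles on
regions sampled by both donors (pairs need ≥ 3 shared regions) — selects
one probe per gene; ties break to higher mean intensity, then lexicographic
probe id. Spearman DS is available as an option. Regional values average
first within, then (unweighted) across donors; regions never sampled stay
absent rather than zero-filled, and per-gene z-scoring across regions is a
flag applied across all regions before any ROI subsetting (the order the
ambiguity permits; subsetting first would change the z-units with the ROI
list).

## 4. Spatial gene association

The group-mean mALFF regional vector is correlated (Pearson) with each gene
column over the intersection of regions present in both; at least 4 shared
regions are required and the intersection size is recorded per gene.
Benjamini–Hochberg q-values are computed with `stats::p.adjust` (verified
against a brute-force step-up oracle on all $2^{10}$ subsets of a fixed
p-vector), and the selection rule is strict: q < 0.05 AND |r| > 0.8. The
whole-cortex run is the default; restricting to an ROI list is a parameter.
No spatial-autocorrelation-preserving null (spin test) is implemented — the
selection matches the reference procedure, and that is a documented
limitation for real atlas data, where smooth spatial autocorrelation
inflates naive gene-wise p-values.

## 5. Gene-set and immune scoring

ssGSEA ranks a unit's genes in descending expression and integrates the
running-sum difference $ES = \sum_i [P_{in}(i) - P_{out}(i)]$, with
$P_{in}$ the cumulative $(N-i+1)^\alpha$ mass of in-set genes
($\alpha = 0.25$ by default; $\alpha = 0$ gives the unweighted walk used by
the hand-checkable closed forms) and $P_{out}$ uniform out-set mass. The
integrated form (not the maximum deviation) is the single-sample
convention; a distribution-based variant (`method = "gsva"`: a Gaussian
cross-unit kernel CDF transform before the same walk) is provided as an
alternative backend since the surrounding literature names both, with
ssGSEA the default. Scores are rank-invariant per unit; optional
normalization divides by the matrix-wide score range.

Marker-set overlap uses the exact hypergeometric upper tail
$P(X \ge k)$; the background universe defaults to the genes surviving
probe filtering — the measured universe, stated explicitly because
over-representation p-values are meaningless without one. Immune
infiltration scores apply ssGSEA to log2-CPM per sample over 24 cell-type
signatures. Group comparisons pass each group through a
D'Agostino–Pearson omnibus gate at 0.05 (re-implemented from the standard
skewness/kurtosis transformations and checked against an independent
implementation; Shapiro–Wilk substitutes below n = 8 where the
transformations are undefined): both normal → equal-variance t, otherwise
Mann–Whitney U, with BH correction across sets. Brain–immune coupling is
Spearman's ρ between per-subject cluster-mean ALFF and per-subject scores,
plus a voxel-wise route that reuses the full correlation → GRF → ROI
machinery.

## 6. Moderated-t differential expression

Counts become $\log_2\mathrm{CPM}$ with prior count 0.5. Per gene the
two-group contrast is estimated by OLS; the residual variance $s^2$ on
$d = n-2$ df is shrunk toward an empirical-Bayes prior obtained by moment
matching of $\log s^2$: with $e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$,
$\mathrm{trigamma}(d_0/2) = \mathrm{var}(e) - \psi'(d/2)$ (inverted by
Newton iteration) and $s_0^2 = \exp\{\bar e + \psi(d_0/2) -
\log(d_0/2)\}$. The posterior variance is $\tilde s^2 = (d_0 s_0^2 + d
s^2)/(d_0 + d)$ and the moderated t has $d_0 + d$ df. When the
log-variance spread does not exceed sampling noise the fit diverges; the
$d_0 = \infty$ branch then uses the fully pooled variance
$\overline{s^2}$, which makes shrinkage an exact no-op when all gene
variances are equal. The implementation reproduces the reference
empirical-Bayes results (prior df, prior variance, t and p) to numerical
precision on shared inputs, which the test suite asserts via the installed
limma as an independent cross-check — the statistic itself is authored
here. No mean–variance precision weighting (voom-style) is applied; with
strong count heteroscedasticity at low depth the moderated t on logCPM is
mildly miscalibrated, a documented limitation. Selection uses the raw p
(< 0.05) and |logFC| > 1, both strict, with q reported alongside —
deliberately the unadjusted rule, because that is the stated convention of
the analysis this package reproduces.

## 7. MCODE modules

Vertex weight = $k \times$ density of the highest-$k$ core of the open
neighbourhood. Complexes grow from unvisited seeds in descending weight
(lexicographic tie-break) by breadth-first inclusion of unvisited
neighbours with weight ≥ (1 − node score cutoff) × seed weight, to the
maximum depth; complexes lacking a 2-core are discarded and survivors rank
by density × size. The four parameters default to degree cutoff 2, node
score cutoff 0.2, k-core 2, max depth 100. Edge confidence weights do not
enter the core algorithm (it is topological); a minimum-confidence edge
filter (default 0.4, a declared choice — the reference network's cutoff is
unstated) applies upstream. Haircut is available behind a flag; fluff is
reserved; both are off by default since only the four parameters above are
part of the stated procedure.

## 8. What the synthetic data emulate — and what they do not

The generators plant every effect the pipeline is supposed to find, at
desk-scale sizes chosen once:

* **Imaging.** Grid 20×20×12 voxels at 3 mm, 24 rectangular-block parcels
  split at the x = 0 plane (left hemisphere gets the ceiling half), 30
  retrospective subjects and 20/20 prospective cases/controls, 200
  timepoints at TR 2 s. Voxel signals are sums of three sinusoids at fixed
  in-band frequencies (snapped to exact FFT bins, keeping amplitudes
  analytically tractable) with region-specific amplitudes — a graded
  pattern over 0.8–1.6 with the planted parcel at the maximum — plus
  white noise (SD 0.5) and per-subject amplitude jitter (SD 0.15 retro /
  0.1 prospective). Realized subject × region amplitudes are recorded and
  drive the clinical couplings.
* **Clinical table.** Indicators are affine in the subject's
  planted-parcel amplitude plus Gaussian noise; zero-slope indicators are
  nulls. CAS is rounded and clamped to the ordinal 0–7 range; because
  rounding destroys roughly one unit of variance, its slope (6) is chosen
  so the *discretized* indicator still carries the planted correlation —
  with a weak slope the ordinal collapse can silently delete the condition
  being tested.
* **Donor expression.** 6 donors × 40 samples, 400 genes × 2 probes.
  Planted genes' regional profiles are affine in the z-scored amplitude
  pattern at coupling r = 0.9; secondary probes add independent noise (so
  DS must prefer the first); a bad-probe fraction (0.1) loses gene ids or
  drops below the recorded background, split half/half, restricted to
  background genes so planted genes stay recoverable. Intensities are
  bimodal (good ≈ N(9, 0.7), bad ≈ N(2, 0.7), threshold 5) to make the
  planted filter fraction exact.
* **Counts.** Negative binomial with $Var = \mu + \phi\mu^2$, $\phi =
  0.1$, library sizes 1–2 M; planted log2 fold changes ±2; immune
  signatures (24 disjoint 30-gene sets named for the ImmuneCellAI cell
  types) shifted by +1.5 (monocytes) and −1.5 log2 units (central-memory,
  effector-memory, γδ T), the directions the prospective arm must
  reproduce; in cases, monocyte-signature genes additionally track the
  subject's planted-parcel amplitude, planting a brain–immune correlation.
* **Graphs.** Erdős–Rényi background (p = 0.05) with a planted 6-node
  module at p = 1.

For the 82-region × 5000-gene recovery study the distilled
`synthRegionalAssoc()` generator feeds the association stage directly (a
smooth Gaussian regional pattern, 50 planted genes at r = 0.9) rather than
routing through donor-microarray emulation — the study targets that stage,
and the direct generator gives exact planted coupling at full scale.

Passing tests on these data show the *machinery* is correct and calibrated.
They do not show robustness to what real data add: fMRI preprocessing
artifacts (motion, drift, physiological noise), microarray batch effects,
spatial autocorrelation of expression (so real gene-wise FDR is optimistic,
see §4), non-block parcel geometry, or donor-to-cohort mismatch.

## 9. Problem sizes and determinism

Simulation-backed checks use: 500 null fields (24³) for GRF calibration
and 12 datasets × 300 permutations for backend agreement; 50–100
replicates for gene-recovery, DE-recall and MCODE studies; 2000 genes for
null type-I error. These sizes give stable aggregates while keeping the
whole suite comfortably re-runnable. Every generator takes a mandatory
seed and is fully deterministic given it; pipeline runs write a manifest
with MD5 hashes of every artifact, and reruns under the same seed are
bit-identical (asserted in the tests and recomputed by the acceptance
script). Known limitations are listed inline above; the largest are the
absence of spin-test nulls for spatial correlation and of voom-style
precision weights for low-depth counts.
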