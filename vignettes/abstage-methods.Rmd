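---
title: "Models and methods behind abstage"
author: "abstage authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind abstage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abstage)
```

# The scientific problem

Cerebral amyloid-β (Aβ) accumulates for a decade or more before amyloid
PET turns abnormal. A drop in CSF Aβ42 below its abnormality cut-off
with still-normal PET (the CSF+/PET− state) is therefore a window onto
the *earliest* stage of accumulation. `abstage` implements the analytic
chain needed to exploit that window: data-driven biomarker cut-offs,
CSF/PET staging, longitudinal regional accumulation-rate contrasts,
voxelwise cluster statistics, atlas-overlap quantification, and a
permutation-based statistic linking whole-brain functional connectivity
to CSF Aβ42. Because the motivating cohorts are access-restricted, a
synthetic generator reproducing their statistical structure is part of
the package, and all guarantees are demonstrated on it.

# Mixture cut-offs and staging

Biomarker abnormality thresholds are estimated from the marginal
distribution alone — diagnosis never enters — by fitting a
two-component Gaussian mixture with EM (`fitMixtureCutoff()`). EM for
mixtures is multimodal, so the fit restarts from a deterministic
median split plus `nRestarts = 10` random soft assignments under a
fixed seed, keeping the best log-likelihood. Restarts that collapse a
component (sd below 1e-6 of the sample sd, or an emptied component) are
discarded; if no restart converges the function errors rather than
returning a doubtful threshold.

The mixture itself does not dictate where to cut. We define the cut-off
as the **posterior-0.5 crossing** between the component means — the
unique solution of `w1 φ(x; μ1, σ1) = w2 φ(x; μ2, σ2)` on `(μ1, μ2)`,
found by root bisection on the log-density difference. This is the
decision boundary under equal misclassification cost, and the only
choice that does not need an external tuning parameter. When the two
components are not separated (no sign change between the means) the
function errors; single-Gaussian data cannot yield a threshold.

Staging (`classifyStage()`) uses *strict* inequalities — CSF+ iff
CSF Aβ42 < cut-off, PET+ iff SUVR > cut-off — so values exactly at a
published cut-off (e.g. 192 ng/L, 0.872 SUVR) remain normal, matching
how such cut-offs are printed ("<192", ">0.872"). Missing biomarkers
produce an explicit `NA` with a warning, never a silent default. The
CSF-low band (`flagCsfLow()`, default 517–750 in the cohort's native
unit, endpoints inclusive) marks normal-CSF subjects near the
threshold; it is only meaningful within the CSF−/PET− stage, which the
pipeline enforces at the point of use.

# Regional accumulation rates

Change is linear: `(followup − baseline)/years` per ROI
(`annualChange()`); no compounding is assumed over the ~2-year
intervals involved. Effect sizes are reported as percent of each
subject's *own* baseline (`percentRate()`), then averaged per group —
the subject-wise reading keeps per-subject values well-defined and
makes group CIs straightforward. Significance, however, is always
assessed on the raw SUVR/yr scale.

`roiContrast()` fits one ordinary least-squares model per ROI
(`rate ~ group + covariates`, classical homoskedastic standard errors
— the "general linear model" convention in this literature; no mixed
effects) and reports the two-sided t-test on the group indicator plus
per-group mean %/yr with normal-theory (t-based) 95% CIs of the mean.
The choice of normal-theory over bootstrap CIs is deliberate and
labelled in the output column names. Rank-deficient designs error with
the collinear columns named; subjects with incomplete covariates are
dropped and counted in the `"n_dropped"` attribute. Multiplicity is
handled by Benjamini–Hochberg step-up (`bhFdr()`, a contract-checked
front end to `stats::p.adjust`) at q = 0.05. Small subgroups (e.g.
~11 CSF converters) route through `rankTests()`, which wraps the
classical rank tests: exact p for small untied samples, normal
approximation with tie correction otherwise.

# Voxelwise maps and clusters

`adjustedTtestMap()` fits the same OLS model at every voxel inside a
mask (vectorised through one QR decomposition) and returns t and
two-sided p maps. `extractClusters()` thresholds at an uncorrected
voxel height (default p < 0.001), labels connected components, and
applies a **strict** extent rule — a cluster must have *more than*
`kMin` voxels (default 100), so a 125-voxel cube survives `kMin = 100`
but not `kMin = 125`. Default connectivity is 26-neighbour with 6 and
18 available; the convention is configurable because different
packages in the field differ and rarely say so. Output order is
deterministic (size descending, ties by peak t), and voxel coordinates
are 0-based throughout the public interface. The extent threshold on
abstract synthetic grids is a free parameter; 100 is kept as the
default for continuity with 2-mm-voxel practice, not because it is
meaningful on a 20³ toy grid.

Cluster–atlas overlap (`overlapDistribution()`) reports, per network,
the overlap count, the percentage of total *labelled* overlap (summing
to 100), and the Jaccard coefficient against the full network mask.
Elements outside every network label are excluded from the percentage
denominator and returned in the `"excluded"` attribute — an explicit
policy where conventions vary.

# The network-component statistic

For per-subject Fisher-z matrices (correlations clipped to
|r| ≤ 1 − 1e-7 before `atanh` so links stay finite), the link-wise
association field r_ij is the **partial Spearman correlation** between
each link's z and CSF Aβ42: both sides are rank-transformed (average
ranks for ties), residualised on the covariates plus intercept, and
correlated (`partialSpearman()`, `linkCorrelations()`). The same
adjusted correlation is used both for thresholding and for scoring —
using an unadjusted field for thresholding but an adjusted score would
make the statistic internally inconsistent. The threshold r₀ inverts
the t-approximation `t = r √(df/(1−r²))` at a two-sided link-level
α (default 0.001), with df = n − 2 − (number of covariates) in
adjusted mode.

Supra-threshold links form components via shared nodes (union-find;
`extractComponents()`), positive and negative directions searched in
separate runs. Each component's size statistic is the product
`S = (Σ r_ij) × ρ(Σ z_ij, CSF)`; the permutation null
(`permutationTest()`) shuffles only the subject-to-CSF assignment —
connectivity matrices and covariates stay with their subjects — and
records the **maximal |S| over all components** per permutation, a
maxT-style construction that guarantees weak-sense FWER control. The p
value is the plus-one estimator `(1 + #{null ≥ |S_obs|})/(1 + n_perm)`,
which can never be exactly zero and is 1 when no observed component
exists. Ties in "largest component" are broken by link count then
summed |r|. By default CSF values are permuted raw — exact under the
complete null that the test addresses, and confirmed by the package's
own FWER simulation (below); an optional Freedman–Lane mode
(`permMode = "freedman_lane"`) permutes covariate-adjusted residuals
instead, for settings where covariates correlate strongly with CSF.

Two properties worth knowing: S is invariant under strictly monotone
transforms of CSF when no covariates are used (both factors are
rank-based), and negating CSF exactly mirrors positive- into
negative-direction results.

# The synthetic generator

`simulateCohort()` emulates the joint CSF/PET structure of a large
non-demented amyloid cohort. Defaults are fixed from the published
characteristics of such cohorts: a normal CSF Aβ42 component
N(234, 27) ng/L against an abnormal N(150, 30) with 53% abnormal
weight; PET components N(0.74, 0.05) / N(1.00, 0.12) SUVR; age
N(72, 7); 47% women; APOE ε4 prevalence 16/46/65/40% by stage; scan
intervals centred on 2.0 years within 0.9–4.1. The observed cohorts
report only the four stage cell counts (roughly 46/12/40/1%), not a
generative dependence, so PET abnormality is drawn *conditionally on
the CSF component* with transition probabilities (2.2% given CSF−,
76.4% given CSF+) that reproduce that mix — a tunable design choice,
not an inference. True stage is the pair of generating components, so
label recovery is exactly measurable downstream.

Rates are linear in time with stage-by-ROI-class means (%/yr); the
default early-ROI set is the 15 DMN-like parcels (posterior/isthmus
cingulate, precuneus, medial/lateral orbitofrontal, rostral anterior
cingulate, insula, plus left superior frontal and right transverse
temporal) and the late set the sensorimotor/occipital parcels.
Noise has three parts: across-ROI baseline scatter (sd 0.05 SUVR),
between-subject rate dispersion (sd 1 %/yr), and additive follow-up
measurement noise (sd 0.04 SUVR). Together these give per-group %rate
dispersions of ~2.5–3 %/yr, the magnitude implied by the confidence
intervals published for cohorts of this size — the generator is
calibrated to realistic uncertainty, not to make tests comfortable.

`simulateConnectivity()` plants a connected link component (default: a
10-link DMN core with two DMN–frontoparietal links in a 30-node,
9-network atlas) whose z values load on a shared subject latent
`effectSize · g(CSF) + √(1 − effectSize²) · η` (g = normal scores of
the CSF ranks, η shared noise) plus a small idiosyncratic term. Making
the planted-link noise mostly *shared* is what lets both the per-link
and the summed-z correlations with CSF concentrate near `effectSize`;
fully independent link noise would push the summed correlation far
above the per-link one. `simulateGrids()` adds a constant group effect
on planted voxel clusters over Gaussian noise.

What the generator deliberately does **not** model: Aβ kinetics, PET
noise physics, partial-volume effects, spatial autocorrelation of
voxel noise, or fMRI time-series structure. Tests passing on this
generator therefore demonstrate the *statistical* correctness of the
machinery (error control, recovery, invariances) — not robustness to
the full messiness of real imaging data.

# Numerical choices and degenerate inputs

* EM convergence: relative log-likelihood change below `tol = 1e-8`;
  cut-off root-found to 1e-10.
* Correlation clipping at |r| = 1 − 1e-7 keeps Fisher z below ~8.4.
* Links with zero variance across subjects get r = 0 rather than NaN.
* `jaccard()` on two empty sets errors (0/0); an empty set against a
  non-empty one is 0.
* Empty component lists, empty cluster lists and the empty-component
  S = 0 convention are all legal outputs, not errors; *missing* data
  (unclassifiable subjects, unlabelled nodes) always surface loudly.
* All stochastic entry points require a seed; identical spec + seed
  reproduces outputs exactly, including across the pipeline manifest.

# Problem sizes used in the shipped checks

The package's own validation runs at deliberately modest scales chosen
to exercise the asymptotics the methods rely on while staying quick on
a laptop: 200 null cohorts × 500 permutations for the FWER check, 2000
replicates for the FDR check, 50 cohorts of 473 subjects × 68 ROIs for
rate recovery, 20 cohorts of 100 subjects for component recovery, 100
random 20³ grids and exhaustive ≤5-node graphs plus 200 random 30-node
fields for the oracle equivalences. The full-scale voxel-level graph
(thousands of nodes) is supported by the same code paths but is not a
test target.

# Known limitations

* Only two-component univariate Gaussian mixtures; heavy-tailed or
  skewed biomarker distributions will bias the cut-off.
* OLS with classical standard errors; no mixed-effects modelling of
  repeated measures beyond the two-timepoint difference.
* The cluster-extent rule controls nothing formally at the cluster
  level (no random-field or permutation cluster correction); it mirrors
  the descriptive thresholding practice it reimplements.
* Both permutation schemes assume exchangeable subjects (simple mode)
  or exchangeable covariate-adjusted residuals (Freedman–Lane mode)
  under the null; neither is exact under strong heteroskedasticity
  across subjects.
* The staging boundary convention (equality = normal) matters only on
  exact ties, which have measure zero for continuous assays but can
  occur with rounded data.
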