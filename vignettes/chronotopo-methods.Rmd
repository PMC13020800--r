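---
title: "Duration pRF mapping and chronotopic map statistics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duration pRF mapping and chronotopic map statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronotopo)
```

## The scientific problem

Neuronal populations in many cortical areas respond preferentially to
particular stimulus durations. When such populations are measured with fMRI,
each surface vertex aggregates thousands of neurons, and their joint
selectivity can be summarized by a *population receptive field* (pRF) over
stimulus duration: a Gaussian tuning curve with a preferred duration
$\mu_d$ (the duration eliciting the largest response) and a width $\sigma_d$
(the sensitivity to departures from the preferred duration). In a
duration-discrimination experiment — six comparison durations between 0.2
and 0.8 s judged against an internalized 0.5 s reference, presented at four
task-irrelevant spatial positions — the vertex-wise response amplitudes
across the 24 duration-by-position conditions carry enough information to
estimate $(\mu_d, \sigma_d)$ per vertex, provided the model is invariant to
position.

`chronotopo` implements that model and everything downstream of it: the
spatial statistics that decide whether preferred durations form orderly
*chronotopic maps* (local and global Moran's I, variograms), the
categorization and hierarchy-gradient summaries that contrast map regimes
across cortex, the long-range rank-correlation structure between regions,
and the link between duration preferences and each individual's perceptual
bias (the point of subjective equality, PSE). Because the original surface
data live in an external deposit, the package ships a synthetic-data module
that plants all of these structures with known ground truth; every analysis
stage is exercised end to end against what was planted.

## The tuning model and its fit

The response model for a vertex is

$$\hat\beta_k \;=\; b \;+\; g\,\exp\!\left(-\frac{(d_k-\mu_d)^2}{2\sigma_d^2}\right),$$

where $d_k$ is the duration of condition $k$ and the four positions sharing
a duration receive identical predictions. The tuning curve itself has no
amplitude or offset; because the inputs are GLM beta weights in percent
signal change, a per-vertex gain $g$ and baseline $b$ are solved in closed
form by least squares at every candidate $(\mu_d, \sigma_d)$ — the standard
pRF practice — and "negative pRF" exclusion is defined as a non-positive
fitted gain.

Fitting is two-stage, per vertex:

1. **Grid search**: $\mu_d$ over 0.1–0.9 s in 0.01 s steps, $\sigma_d$ over
   0.02–0.5 s in 30 log-spaced steps; at each node the RSS after the
   closed-form gain/baseline solve; ties broken toward smaller $\sigma_d$,
   then smaller $\mu_d$, so results are deterministic.
2. **Bounded simplex refinement**: Nelder–Mead on $(\mu_d, \sigma_d)$ seeded
   at the best grid node, with the box $\mu_d \in [0.05, 1.0]$,
   $\sigma_d \in [0.01, 1.0]$ realized by a logistic coordinate transform
   (the simplex explores an unbounded space whose image is the box
   interior). Relative RSS tolerance $10^{-8}$, at most 2000 evaluations.
   Only vertices whose grid fit explains at least 10% of variance are
   refined; the rest are excluded as `low_r2`. If the simplex fails to
   improve on its seed, the seed is kept, so `r2_final >= r2_grid` always.

The experimental manipulations are also expressible as a
$100 \times 100 \times 24$ stimulus tensor (space units × duration units ×
conditions), mirroring how the modeling pipeline represents the task.
Durations map affinely onto the duration-unit axis at 150 units/s, placing
0.2 s at unit 10 and 0.8 s at unit 100. This constant was chosen so that
all six design durations land on integer tensor columns; summing a
position-invariant pRF image over a (mass-one) condition slice then
reproduces the closed-form Gaussian prediction to machine precision. The
tensor is fidelity machinery, not a second model, and the package tests
enforce the equivalence at $10^{-12}$.

**Identifiability.** Preferred durations near the edges of the presented
range (and beyond) are progressively less identifiable, since the design
only samples 0.2–0.8 s; recovery is exact in the interior at zero noise and
degrades gracefully outside. With additive beta noise of 0.05 psc and unit
gain, the median $|\hat\mu_d - \mu_d|$ is below 0.02 s, and recovery error
grows monotonically with noise.

## Spatial statistics on preference maps

**Local Moran's I.** With preferences centered to the hemisphere mean
($z_i$), second moment $m_2 = \sum_i z_i^2 / n$, and row-standardized
k-nearest-neighbor weights, $I_i = (z_i/m_2)\sum_j w_{ij} z_j$. The
neighborhood size follows the study rule — one-fourth of the smallest ROI
in the hemisphere — which trades fine-grained structure for comparability
across ROIs. Significance uses conditional permutation: the focal value is
held fixed while neighbor values are resampled without replacement from all
other vertices in scope, 999 times. Significant vertices are classified
HH/LL/HL/LH by the signs of $z_i$ and its spatial lag.

*Sidedness.* Whether the pseudo p-value should be one- or two-sided is
genuinely open; side-selected one-sided p-values (choosing the tail after
seeing the statistic) double the nominal false-positive rate (we measure
~0.10 at $\alpha = 0.05$ on spatially random fields). The package therefore
uses the two-sided pseudo p-value $\min\{1, 2(R+1)/(999+1)\}$, whose null
rejection rate is calibrated (measured 0.050). This is the package's
choice, recorded here.

**Global Moran's I** is the average of the local statistics, which with
row-standardized weights equals the textbook global statistic; the package
verifies this against an independent reference implementation on every
tested instance. It is computed per ROI with 12 nearest neighbors and
ROI-mean centering, with a total (all-values) permutation null and a
two-sided pseudo p.

**Variogram.** Preferences are z-scored within scope (sample-SD scaling, so
the pooled all-pair semivariance equals the unit total variance exactly),
pairwise distances grouped into 2 mm bins, and each bin given the Matheron
estimator $\gamma(h) = \sum_{pairs} (z_i - z_j)^2 / (2N(h))$. The *nugget*
is the first nonempty bin's $\gamma$ as a fraction of total variance
(near 1 for unstructured maps, near 0 for smooth ones); the *range* is the
first binned distance at which $\gamma$ reaches the total variance,
expressed as a fraction of the maximum inter-vertex distance (reported as 1
with a flag when never reached). Distances default to Euclidean between
stored coordinates; a precomputed geodesic matrix can be attached to the
patch. A plain within-bin pairwise-variance estimator is available behind a
flag for comparison; Matheron is the default and the tested path.

**Categories and gradients.** Preferences are binned into five categories
(short 0.2–0.32, mid-short 0.32–0.44, medium 0.44–0.56, mid-long 0.56–0.68,
long 0.68–0.8 s). Intervals are left-closed and right-open with the final
interval closed — a convention the package fixes explicitly because fitted
values do land on interior edges; out-of-range values are flagged, never
silently binned. Per-ROI summaries (median preference, category fractions,
LL−HH difference) are regressed on an explicit, user-supplied
occipital-to-frontal hierarchy ordering by OLS; the ordering is an input
because it is an anatomical judgment, not a formula.

**Long-range structure.** Subject-by-region median preferences give a
Kendall tau-b correlation matrix; the matrix rows are treated as
coordinates and converted to Euclidean inter-region distances (the behavior
of passing a matrix directly to a row-wise distance computation; a
$1-\tau$ option exists), then clustered with complete linkage.

**Behavior.** Psychometric curves are binomial GLMs with a logit link;
PSE $= -\text{intercept}/\text{slope}$. Per-region Kendall correlations
between subjects' PSEs and median preferences are transformed by
$z(\tau) = \tanh^{-1}(\sin(\pi\tau/2))$ — odd and strictly increasing on
$(-1,1)$ — before their hierarchy regression. $|\tau| = 1$ maps to
$\pm\infty$: the default is a hard error, with an optional clamp at
$1 - 10^{-6}$ for exploratory runs. P-values are uncorrected (a
Benjamini–Hochberg option exists but is off by default); exact permutation
is used for $n \le 9$ and a tie-corrected normal approximation above.

## What the synthetic generator emulates

A `surface_patch` is a flat regular lattice with contiguous ROI bands — a
stand-in for a flattened, resampled cortical patch. Planted preference
fields come in five regimes: linear gradients (orderly chronotopic
progressions), Gaussian random fields (smoothed white noise rescaled to
unit variance, mixed with fresh white noise at a controllable nugget
fraction — a seedable construction with an explicit correlation length),
white fields (no topography), boundary fields (preferences i.i.d. tight
around 0.5 s), and constants. Preferred durations are clipped to
0.2–0.8 s after generation so ground truth stays identifiable; the clipped
fraction is recorded. The tuning width $\sigma_d$ is drawn i.i.d. uniform
on 0.05–0.3 s — the empirical distribution of $\sigma_d$ is not known, so
this default is a free choice, flagged as such. Forward simulation applies
the tuning model per vertex with additive Gaussian noise; behavior is
Bernoulli draws from a logistic with a planted PSE and slope. All
randomness flows from one explicit integer seed per call.

The generator does **not** emulate BOLD time series, hemodynamics, GLM
estimation noise structure, curved/triangulated meshes, or geodesic
distances on folded surfaces. Passing tests therefore demonstrate the
correctness and calibration of the analysis machinery on fields with known
structure — not that real cortical data satisfy the model.

## The default study configuration

`default_pipeline_config()` encodes the synthetic study the package's
acceptance checks run: 13 subjects; one hemisphere with seven equal ROIs
(72 vertices each, 2 mm spacing) ordered occipital to frontal; beta noise
0.05 psc; 999 permutations at $\alpha = 0.05$; 2 mm variogram bins; 12
neighbors for the global statistic and the quarter-of-smallest-ROI rule
(here k = 18) for the local one; 80 trials per comparison duration.

The planted hierarchy mirrors the regimes the analyses are built to
detect: occipital visual ROIs carry smooth, long-skewed maps (random
fields centered at 0.63/0.60 s); parietal ROIs carry full-range gradients;
a motor-somatosensory ROI carries a short-skewed map (centered 0.35 s);
frontal ROIs are boundary-tuned at 0.5 s with 0.03 s spread. With this
layout the hemisphere mean sits just above 0.5 s, so long-skewed occipital
maps classify HH-dominant, the short-skewed map LL-dominant, gradients
stay balanced, and the LL−HH difference increases along the hierarchy —
the contrast between full-range and boundary-centered regimes the summary
statistics are designed to expose. One frontal ROI's boundary center
equals each subject's planted PSE, so the preference–perception link
exists by construction exactly where it is looked for.

Problem sizes in the tests and the acceptance script (patch sizes, seed
counts, trials) were chosen so each property is measured with comfortable
Monte-Carlo margins while the whole suite completes in a few minutes.

## Numerical choices and degenerate inputs

* Zero-variance amplitude vectors cannot define $R^2$ and are flagged
  `fit_failure`; constant preference fields are rejected by Moran and
  variogram computations with explicit errors.
* Grid-search ties break toward smaller $\sigma_d$ then smaller $\mu_d$;
  k-NN distance ties break by ascending vertex id; both make reruns
  bit-identical.
* Flat hierarchy regressions return slope 0 with $t = 0$, $p = 1$ rather
  than erroring; exactly collinear data return $p = 0$.
* The map renderer masks grid cells whose total kernel weight falls below
  a threshold (default 0.05), marking locations outside the sampled
  surface.
* All pipeline randomness derives from one master seed through a fixed
  integer hash, and every stage's sub-seed is recorded in its JSON
  sidecar; identical configurations reproduce identical output hashes.

## Known limitations

* Lattice patches with Euclidean (or user-supplied) distances stand in for
  folded cortical surfaces; geodesic effects are not modeled.
* The pRF stage starts from condition-wise amplitudes; GLM estimation and
  its noise correlations are upstream of the package's scope.
* Group inference on the exported summary tables (mixed-effects models,
  ANOVAs) is intentionally left to external statistical tooling; the
  package emits tidy tables instead.
* A rich search grid will fit more than 10% of variance in a substantial
  fraction of pure-noise vertices (best-of-many selection inflates
  $R^2$), so the 10% retention rule alone is a weak noise filter; on
  unstructured inputs it excludes roughly a third of vertices, not nearly
  all of them. Downstream conclusions should lean on the spatial
  statistics' permutation nulls, which are calibrated.
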