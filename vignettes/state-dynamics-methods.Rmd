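---
title: "Multi-voxel state dynamics and resilience: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-voxel state dynamics and resilience: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statevel)
```

## The problem this package addresses

Resting-state fMRI records spontaneous BOLD activity without a task. Two
complementary views of a network's temporal dynamics are implemented here
for any set of regions of interest (the default mode network, DMN, being
the motivating case):

* **Multi-voxel state dynamics.** The voxel pattern of the network at
  timepoint $t$ is a *state vector* $s_t$. After normalising the whole
  voxels-by-time matrix to SD units, the $n$ states are embedded in a
  low-dimensional space by non-metric multidimensional scaling (NMDS),
  and the transition velocity between consecutive states is the
  Euclidean step length
  $V_{s_t \to s_{t+1}} = \sqrt{\sum_k \left(d_{t+1}(k) - d_t(k)\right)^2}$,
  where $d_t(k)$ are the embedded coordinates. With one volume every TR
  the velocities are in SD per TR (SD/2 s at TR = 2 s). The per-subject
  summary is the mean transition velocity
  $\mu_V = \frac{1}{n-1}\sum_t V_{s_t \to s_{t+1}}$. Low $\mu_V$ means
  highly autocorrelated consecutive states.
* **Region-mean variability.** Each ROI's mean time series is z-scored
  across time and the z-scores are averaged across ROIs at each
  timepoint, giving $\bar z_t$. Its order-sensitive variability is the
  root mean square of successive differences,
  $\mathrm{rMSSD} = \sqrt{\frac{1}{n-1}\sum_t (\bar z_{t+1} - \bar z_t)^2}$,
  and its order-free counterpart is the sample standard deviation (SD).
  The two coincide in rate only through the lag-1 autocorrelation $r_1$:
  on AR(1) series $\mathrm{rMSSD}/\mathrm{SD} \to \sqrt{2(1 - r_1)}$.

On the behavioural side, three self-report resilience instruments are
scored — CD-RISC (25 items, 0–4, total 0–100), BRS (6 items, 1–5, mean
1–5, reverse-keyed items 2/4/6), RSA (29 items, 1–7, total 29–203 over
five subscales) — and summarised by principal components of the
correlation matrix. PC1 of such batteries is a general perceived
resilience factor; PC2 contrasts the BRS (perceived ability to recover
by oneself) against the RSA (dominated by inter-personal support), and
is sharpened by a composite score
$\tfrac12(\mathrm{PS} + \mathrm{FSS}) - \tfrac13(\mathrm{FC} +
\mathrm{SC} + \mathrm{SR})$ over the RSA subscales. Dynamics metrics and
resilience measures are then related by Pearson correlation grids with
Benjamini–Hochberg FDR adjustment and, where confounding is a concern
(mean framewise displacement, ROI size), by partial correlations.

## Signal conditioning

`condition_series()` applies a fixed stage order: dummy discard →
confound regression → linear detrend → zero-phase bandpass → ROI
masking. Contracts rather than tool internals are implemented: the
conditioning stage reproduces the mathematics of a standard resting-state
stream (confound regression against realignment parameters, framewise
displacement and optional extra noise components; 0.009–0.08 Hz
bandpass), not any specific neuroimaging tool. Registration,
slice-timing, segmentation and anatomical component estimation are out
of scope; masks are assumed co-registered, and voxels are always
extracted in ascending linear-index (column-major) order so matrices are
reproducible across platforms.

Parameter choices:

* **Framewise displacement** uses Power-style backward differences with
  rotations converted to arc length on a 50 mm sphere — the dominant
  convention; the radius is exposed.
* **Motion exclusion** reads its thresholds (3.4375 mm translation — one
  functional voxel width — and 3° rotation) as *peak absolute
  realignment parameters* with strict inequality; whether the original
  rule applies to peaks or framewise values is ambiguous in the source
  conventions, so the peak reading is used and flagged for sensitivity
  analysis.
* **Bandpass**: a second-order Butterworth applied forward–backward
  (zero phase). The testable contract is the gain profile, not the
  filter family: a 0.04 Hz sinusoid must pass with gain in [0.9, 1.1],
  and 0.002 Hz or 0.2 Hz sinusoids must be attenuated below gain 0.2.

## The embedding and its numerical choices

The dissimilarity between states is the Euclidean distance between
z-scored state vectors — the choice under which the step lengths of the
velocity formula have their cleanest interpretation, and under which
classical scaling at full rank reproduces the distances exactly (the
package's test oracle). The production embedding is non-metric
(Kruskal stress-1, `vegan::monoMDS`), because a *projection stress*
criterion is the NMDS goodness-of-fit, evaluated over candidate
dimensions $k \in \{2, 3, 4\}$.

Numerical decisions, all exposed as arguments:

* **Dimensionality rule**: the smallest candidate $k$ with stress
  below 0.10 (the conventional "fair" cut); if none qualifies, the
  minimal-stress candidate. Per-subject selection by a fixed threshold
  keeps the rule mechanical and reproducible.
* **Initialisation**: `restarts` initialisations per dimension, the
  first from classical (metric) scaling and the remainder seeded random;
  the lowest stress wins and ties favour the metric start. A pure
  random-start NMDS is scale- and ratio-free for very small
  configurations, and the metric start both stabilises the solution and
  makes lean single-start configurations deterministic.
* **Scale calibration**: NMDS minimises a scale-invariant criterion and
  `monoMDS` normalises its coordinates, so the winning configuration is
  rescaled by the least-squares factor matching embedded to input
  dissimilarities. This keeps coordinates — and therefore velocities —
  in SD units.
* **Degenerate input**: a time-constant matrix cannot be z-normalised
  (`znormalize_matrix()` raises a degenerate-input error, as does
  `roi_mean_zseries()` for a constant ROI). The `state_dynamics()`
  wrapper resolves the degeneracy explicitly: states that never move
  have $\mu_V = \mathrm{rMSSD} = \mathrm{SD} = 0$.
* **Normalisation scope**: grand (whole-matrix) z-normalisation, i.e.
  one mean and one SD over all voxels and timepoints jointly, following
  the "normalised to the total matrix mean" reading; per-voxel
  normalisation is available behind `per_voxel = TRUE` for sensitivity
  analyses.
* **Divisors**: the velocity mean and rMSSD use $n - 1$ (the number of
  transitions); the SD metric is the sample standard deviation, also
  with $n - 1$.

## Scoring and PCA conventions

PCA is computed on the correlation matrix: the three scales have
incommensurate ranges (0–100, 1–5, 29–203), so covariance-matrix PCA
would be dominated by the widest scale. Loadings are reported as
measure–component correlations (eigenvectors scaled by the square root
of their eigenvalues), so squared loadings per component sum to the
eigenvalue and `loadings %*% t(loadings)` reproduces the correlation
matrix. Component signs are fixed so each component's largest-magnitude
loading is positive; since PCA signs are arbitrary, replicate-stable
analyses should orient a component by a substantive contrast
(`orient_component()`, e.g. PC2 oriented so its BRS loading exceeds its
RSA loading). Missing items are a hard error — silent imputation changes
totals; the RSA item-to-subscale map ships as an editable configuration
fixture because the instrument's mapping is licensed, and RSA subscale
scores enter the composite as sums (item-mean subscales would only
rescale the composite).

For the association stage, each reported grid (one dynamics metric
against the full set of measures and components) is one BH-FDR family —
the most conservative family definition consistent with per-test
adjusted p-values — and family membership is recorded in the output.
Tests are two-sided throughout. "As a covariate" is implemented as the
partial correlation (both variables residualised); the semi-partial
variant is available behind a flag.

## The synthetic cohort generator

Because the motivating datasets are request-only, the generator is a
first-class module producing cohorts with known ground truth:

* **Neural side.** Per subject, an $m = 3$ dimensional latent AR(1)
  process with persistence $\rho$ and unit marginal variance is mapped
  through a fixed random voxel-loading matrix with unit-norm rows, plus
  a globally coherent AR(1) component with subject amplitude $a$ and
  white voxel noise at a stated SNR. $m = 3$ matches the 2–4 dimensional
  embedding range, keeping the embedding well-posed. The marginal
  variance is held fixed across $\rho$ so that velocity differences
  reflect persistence, not amplitude.
* **Planted effects.** Independent standardised latent factors (general
  resilience $g$, self-recovery $s$, external support $u$) drive two
  neural channels. The *velocity driver* $v$ satisfies
  $\mathrm{cor}(v, s) = \texttt{effect\_r}$ (default $-0.3$) and maps to
  persistence via $\rho = \mathrm{clamp}(0.5 - 0.2v,\ 0.02,\ 0.97)$, so
  $\mu_V$ is monotone-increasing in $v$ and the planted correlation is
  expressed, to within the pipeline's attenuation, in the observable
  $\mu_V$. `effect_r` is defined on the velocity scale (negative values
  plant "smaller transitions ↔ more self-recovery") because that is the
  direction the downstream recovery tests verify. The *variance driver*
  $w$ satisfies $\mathrm{cor}(w, g) = \texttt{general\_link\_r}$
  (default $-0.15$) and sets the global-coherence amplitude
  $a = 0.3\,e^{0.5 w}$; stronger coherent fluctuation raises the
  variance of $\bar z_t$ and with it rMSSD and SD. A `driver_cor`
  (default 0.3) correlates the residual parts of $v$ and $w$, giving the
  positive $\mu_V$–rMSSD correlation seen in real data while leaving the
  planted factor links intact.
* **Questionnaire side.** Items are latent-continuous values discretised
  at equal-probability quantiles of the latent normal (uniform item
  marginals at zero effect — the simplest defensible null). Loadings:
  CD-RISC items 0.75 on $g$; BRS items 0.50 on $g$ and 0.65 on $s$ (the
  BRS saturates its defining bounce-back construct); RSA intra-personal
  items 0.60 on $g$ and 0.30 on $s$; RSA inter-personal items 0.60 on
  $g$ and 0.55 on $u$. All instruments share the general factor — a
  support-only loading for the inter-personal items would leave the
  three totals nearly uncorrelated and make the second component a pure
  support axis, contradicting the strongly intercorrelated structure
  such batteries show (all-positive dominant PC1 near 75% variance, PC2
  contrasting BRS against RSA). Under these loadings the generator
  reproduces that qualitative structure, and BRS items are produced
  already in scored orientation (reverse-keying is the scoring module's
  job, exercised with `reverse_keyed = TRUE` on real data).
* **Motion.** Slowly drifting random walks whose framewise displacement
  scales with `fd_scale`, clamped well inside the exclusion thresholds,
  plus exactly `n_spikes` single-frame excursions at seeded interior
  timepoints (never the first frame, where FD is undefined).

What the generator does *not* emulate: hemodynamic response shapes,
spatial autocorrelation between voxels, scanner drift or physiological
artifacts beyond the white/AR structure. Passing parameter-recovery
tests therefore demonstrates that the pipeline's mathematics recovers
planted structure under idealised noise — not that the method is robust
to the full artifact spectrum of real fMRI.

## Problem sizes used by the test suite

The replicate studies in the package's tests use cohorts of 336 subjects
with 240 timepoints (the design scale), 96 voxels in 16 pseudo-ROIs, and
a lean embedding configuration (fixed $k = 3$, the metric start only,
50 majorisation iterations); the recovery and dissociation proportions
are evaluated over 20 seeded replicates, and null FDR calibration over
1000 replicates of pure-noise association tables. These sizes are the
package's choice of a desktop-scale design: the lean embedding tracks
the full configuration closely on generator data (intrinsic dimension 3),
and 20 replicates bound a ≥ 90% recovery proportion while keeping the
suite's runtime modest. Monotonicity of $\mu_V$ in $\rho$ is checked at
200 voxels over $\rho \in \{0, 0.3, 0.6, 0.9\}$ with 20 paired
replicates and a sign test.

## Known limitations

* NMDS at $k \le 4$ compresses genuinely high-dimensional transition
  structure; on data whose intrinsic dimension far exceeds the candidate
  set the velocities are rank-faithful but not metrically faithful
  (the full-rank classical-scaling oracle is exact; the NMDS production
  path is validated by rank correlation on low-rank data).
* The per-subject stress-threshold rule can select different $k$ for
  different subjects; velocities remain comparable because coordinates
  are calibrated to the common dissimilarity (SD) units, but users
  wanting a fixed dimension can pass a single candidate.
* Scoring assumes complete item responses; the package deliberately has
  no imputation path beyond a hard error.
* The association stage implements correlation-family analyses only — no
  mixed models, mediation, or voxelwise statistics.
* Conditioning implements the mathematical contract of a standard
  resting-state stream; it is not a substitute for registration,
  segmentation, or physiological noise modelling, which must happen
  upstream of this package.
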