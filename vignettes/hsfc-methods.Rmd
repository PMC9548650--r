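---
title: "Hemispheric similarity of functional connectivity: model, estimation and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemispheric similarity of functional connectivity: model, estimation and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsfc)
```

## The measure

Resting-state functional connectivity (FC) between two brain regions is the
Pearson correlation of their mean BOLD time series. Given a parcellation
with R regions — R/2 homotopic pairs per hemisphere — each subject yields an
R × R symmetric FC matrix; its two intra-hemisphere blocks, ordered by
homotopic pair index and Fisher-z transformed, are directly comparable
element by element. The **hemispheric similarity of functional connectivity
(HSFC)** is the Pearson correlation between the two hemispheres' edge
vectors (strict upper triangles, n(n−1)/2 edges):

$$\mathrm{HSFC}_i \;=\; \mathrm{cor}\!\big(\mathrm{vec}(Z^{L}_i),\, \mathrm{vec}(Z^{R}_i)\big).$$

A value of 1 means the two intra-hemisphere connectomes are perfectly
mirrored; lower values indicate functional lateralization. The same
definition restricted to the block of regions in one functional sub-module
(heteromodal, paralimbic, primary, unimodal, subcortical — the classic
functional-hierarchy classes) gives a sub-module HSFC.

Three choices here were genuinely open and are worth stating:

* **Edge set.** Only within-hemisphere, strictly-upper-triangle edges enter
  the correlation. The diagonal is excluded because the Fisher-z of a
  self-correlation is infinite and self-edges carry no information; using
  the full symmetric matrix would merely duplicate every edge without
  changing the correlation.
* **Analysis scale.** HSFC and identification operate on Fisher-z matrices
  by default (z = atanh r is the standard variance-stabilizing
  normalization); `use_fisher = FALSE` / `scale = "pearson_r"` switch to raw
  correlations for sensitivity checks. Off-diagonal |r| = 1 is clipped to
  1 − 10⁻⁷ before the transform — this keeps z finite while preserving the
  ordering of correlations, and only engages on degenerate (exactly
  collinear) inputs.
* **Sub-module edge scope.** Sub-module HSFC uses the within-module block
  only (edges among that module's regions), not the module-to-rest edges:
  the block is what the module-level hemisphere comparison depicts, and it
  keeps the five sub-module statistics on disjoint edge sets.

## Fingerprint identification and its permutation null

Identification follows the connectome-fingerprinting recipe, applied across
hemispheres within subject: the target is one hemisphere's edge vector, the
database holds the contralateral vectors of all N subjects (and, in the
"with ipsilateral" condition, every same-hemisphere vector except the
target's own), and the predicted identity is the database entry with the
maximal Pearson correlation. Exact ties are broken by database order and
flagged `ambiguous`; with continuous data they have probability zero, but
the rule must be deterministic.

Significance is assessed by shuffling which database matrix belongs to which
subject — a uniform random permutation of the subject labels on database
entries — and recording the success rate of each of 1,000 shuffles. Because
relabelling changes no correlation, each target's best-matching *entry* is
fixed, and the null success count of a permutation π is simply the number of
targets whose best-matching subject is mapped back to them by π. The
implementation therefore precomputes the N × M correlation matrix once and
evaluates each permutation in O(N); the test suite verifies this shortcut
agrees *exactly* with a slow re-identification under relabelled databases.
The empirical p is the raw proportion of null rates ≥ the observed rate (it
can legitimately be 0); an add-one-corrected p is reported alongside. In the
"with ipsilateral" condition the shuffle is applied to the same augmented
database the observed run used.

For an exchangeable cohort the null success count behaves like the number of
fixed points of a random permutation composed with a fixed matching map —
mean ≈ 1, approximately Poisson — so with N = 166 the largest of 1,000 null
rates is expected around 5–6 correct (≈ 3–4%).

## The synthetic cohort generator

The generator exists so that every stage — file I/O aside — can be exercised
and validated without fMRI data. It emulates a lifespan cohort (ages uniform
on [18, 88], the Young/Middle/Old groups splitting at 40 and 60) with the
three ingredients the analysis is sensitive to.

Each hemisphere's signal follows a K-factor model. For subject *i*,
hemisphere *h*, the (R/2) × K loading matrix is

$$B_{ih} \;=\; a_i\,B_g \;+\; b_i\,B_i \;+\; c_i\,\mathrm{diag}(m)\,B^{asym}_{ih},$$

where `B_g` is shared by all subjects (group template), `B_i` by a subject's
two hemispheres (the fingerprint), and `B_ih^asym` is hemisphere-specific
(asymmetry); homotopic partners use the same rows of `B_g` and `B_i`. All
component entries are i.i.d. N(0, 1/K); `diag(m)` applies a per-sub-module
asymmetry multiplier, and each row of `B_ih` is then renormalized to unit
length so every region's signal variance is 1. Time series are
`x_t = B_ih u_t + sqrt(psi) eps_t` with standard-normal factor scores and
white noise, so the population FC of a hemisphere is
`(B_ih B_ih' + psi I) / (1 + psi)` — positive definite by construction, no
nearest-PD projection needed. The realized loadings are returned in the
cohort object so tests can compare empirical FC against this closed form.

Factor scores `u_t` are drawn **independently per hemisphere**. This is a
deliberate design decision: if the two hemispheres shared factor
realizations, their *empirical* FC matrices would co-fluctuate even with no
shared loadings, so subjects would remain identifiable at `b2 = 0` and the
exchangeable-null condition would be impossible to generate. With
independent scores, hemispheric similarity and identifiability flow through
the loadings alone — exactly the structure HSFC is meant to measure. The
cost is that the generator does not produce elevated homotopic
*inter*-hemispheric FC; those edges are discarded by the hemisphere split
anyway.

Age enters only through the asymmetry weight:
`c_i^2 = c02 + age_slope * u_i` with normalized age `u_i = (age−18)/70`,
clipped to `[0, 1 − a2]`, after which `(a2, b2)` are rescaled, ratio
preserved, so the weights sum to 1. A positive `age_slope` therefore lowers
HSFC with age by construction — the generator reproduces an age-declining
hemispheric similarity as a *recoverable truth*, not as an empirical claim
about brains. A sub-module positive trend (as sometimes reported for
subcortex) is not modeled by default but can be mimicked with per-module
multipliers.

### Defaults and why

| parameter | default | rationale |
|---|---|---|
| `a2, b2, c02` | 0.4, 0.5, 0.1 | strong but imperfect fingerprint: identification succeeds at realistic cohort sizes while HSFC stays well below 1 (~0.7 at T = 200) |
| `age_slope` | 0 | no age effect unless the experiment asks for one; 0.4 spans a large HSFC decline over the 70-year range while keeping `c02 + slope ≤ 1 − a2` |
| `noise_variance` | 0.2 | ~17% of total variance as scanner/physiological noise |
| `regions_per_hemisphere` | 40 | large enough for 780-edge vectors (stable correlations), small enough that a 200-subject cohort runs in ~1 s |
| `submodule_pairs` | 12/6/8/10/4 | roughly the relative cortical extents of the five hierarchy classes, subcortex smallest |
| `n_factors` K | 10 | low-rank connectivity with plausibly structured correlation; K ≪ R/2 keeps edge correlations well away from identity |
| `n_timepoints` T | 200 | a typical single-session resting-state run length after scrubbing |

What passing tests on this generator do **not** show: robustness to
autocorrelated BOLD noise, head motion, imperfect homotopic registration, or
non-uniform age distributions. The generator is a statistical emulator of
the analysis' assumptions, not a hemodynamic simulator.

## Aging and demographic statistics

The age trend is the Pearson correlation between age and HSFC, with the
usual two-sided t test on n − 2 degrees of freedom. Group summaries use the
sample (n − 1) SD. Demographic tables are compared with a Pearson chi-square
*without* continuity correction for sex-by-group counts (the convention for
2 × K tables of this size; the published counts reproduce to the printed
p = 0.871 only without the correction), and a one-way F-test for age
reconstructed from per-group (mean, SD, n) summaries — between-group sums of
squares from the group means, within-group as Σ(nᵢ−1)sᵢ² — which is
algebraically identical to the raw-data ANOVA, as the test suite verifies.

Age-group boundaries are half-open, [18, 40), [40, 60), [60, 88]: the
source convention gives only integer labels (18–39, 40–59, 60–88), and
half-open intervals extend them to continuous ages without gaps. Ages
outside [18, 88] are rejected rather than extrapolated.

## Cross-parcellation robustness

Whether HSFC is an artifact of one atlas is checked by recomputing it under
a second scheme and correlating subjects' values. Without a second real
atlas, `derive_coarse_scheme()` builds one by construction: it merges
`merge_factor` consecutive homotopic pairs *within* hemisphere and
sub-module into one coarse region whose series is its members' mean —
never merging across sub-module boundaries, so every module's pair count
must be divisible by the factor. The comparison is only meaningful on a
cohort with true between-subject HSFC heterogeneity (e.g. the age-drift
setting): if every subject shares one population HSFC, the correlation of
the two estimates measures shared estimation noise, not robustness. On a
100-subject lifespan cohort (`age_slope = 0.4`) the fine-vs-2:1-coarse
hemisphere-level correlation is ≈ 0.94.

## Numerical choices and problem sizes

* Zero-variance detection is relative: a region counts as constant when its
  variance is below 10⁻²⁴ times its mean square (or, after global-signal
  regression, times its pre-regression mean square), so OLS round-off does
  not mask a genuinely flattened region.
* Parcel-level global-signal regression fits each region on an intercept
  plus the mean of all parcel series. When that mean is constant the
  regression is refused; when it is zero only up to round-off (e.g. the
  input is already GSR residuals) the fit degenerates to demeaning, which
  makes the operation idempotent. This parcel-level operation reproduces
  the with/without-GSR contrast qualitatively; it is not a substitute for
  voxelwise nuisance regression, which belongs upstream.
* Matrix TSVs store 17 significant digits; round trips are identity to
  better than 10⁻¹².
* The population-FC validation compares empirical FC at T = 2000 against
  the closed form above. Per-edge sampling error has sd ≈ (1−ρ²)/√T ≈ 0.02,
  so across the ~1,560 edges of a 5-subject spot-check the expected *maximum*
  deviation is ≈ 0.08–0.09; the test asserts max < 0.12 (≈5σ) and mean
  < 0.03 rather than an unattainably tight max bound.
* Test and acceptance problem sizes — cohorts of 12–200 subjects, 40
  regions per hemisphere, T = 200–300, 200 replicates for the type-I check —
  were chosen as the smallest designs at which each property is
  statistically decisive (identification saturates, the null max
  concentrates, the type-I rate has a tight binomial CI).

## Known limitations

* Homotopic pairing must be supplied (or generated); real atlases' region →
  sub-module lookups are user data, not package constants.
* White, temporally uncorrelated noise overstates the effective number of
  independent timepoints relative to real BOLD.
* Only linear age trends are modeled and estimated; quadratic or spline
  trajectories are out of scope.
* The GSR toggle operates on parcel series, so it cannot reproduce
  voxelwise-GSR results bit-for-bit, only the direction of the contrast.
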