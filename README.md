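# hsfc: hemispheric similarity of functional connectivity

`hsfc` is an R package for studying how similar the two halves of the human
functional connectome are — and what that similarity is worth as an
individual "fingerprint" across the adult lifespan. It is aimed at
resting-state fMRI researchers who already have parcel-level (ROI) time
series and want a tested, scriptable implementation of the
hemispheric-similarity analysis: per-hemisphere connectivity matrices,
the HSFC statistic at hemisphere and functional sub-module level,
cross-hemisphere individual identification with a permutation null, aging
trends, and cross-parcellation robustness checks.

## The statistic

For one subject, functional connectivity (FC) between two regions is the
Pearson correlation of their mean time series. With a parcellation of R
regions (R/2 homotopic pairs per hemisphere), each subject yields two
(R/2) × (R/2) intra-hemisphere FC matrices, Fisher-z transformed
(z = atanh r) and ordered by homotopic pair so row k on the left and right
refer to anatomically corresponding regions. Writing vec(·) for the strict
upper triangle of a matrix,

    HSFC = cor( vec(Z_LH), vec(Z_RH) )

— the Pearson correlation between the left- and right-hemisphere edge
vectors. HSFC = 1 means perfectly mirrored connectomes; lower values mean
greater functional lateralization. The same definition applies within each
of five functional sub-modules (heteromodal, paralimbic, primary, unimodal,
subcortical).

Identification treats one hemisphere as the query and the other as the
database: subject i is correctly identified when their left-hemisphere edge
vector correlates more strongly with their own right-hemisphere entry than
with any other subject's (`ID = argmax_j cor(vec(Z_LH,i), vec(Z_RH,j))`),
optionally with all other subjects' ipsilateral matrices added to the
database. Significance comes from shuffling which database matrix belongs to
whom, 1,000 times.

Because raw fMRI cohorts cannot ship with a package, `hsfc` includes a
factor-model cohort generator whose group-template, subject-fingerprint and
hemisphere-asymmetry components (with an optional age drift of the asymmetry
share) reproduce the statistical structure the analysis assumes, so every
stage is testable end-to-end. Real data enter through plain TSV files
(`read_scheme()`, `read_timeseries()`).

## Worked example

Forty synthetic subjects whose hemispheric asymmetry grows with age
(`age_slope = 0.4`):

```r
library(hsfc)

cfg    <- cohort_config(n_subjects = 40, age_slope = 0.4, seed = 99)
cohort <- generate_cohort(cfg)

# HSFC at hemisphere + sub-module level for every subject
records <- hsfc_cohort(cohort)

# cross-hemisphere fingerprinting, LH -> RH
edges <- edge_vectors(cohort, level = "hemisphere")
run_identification(edges, direction = "lr")
#> Cross-hemisphere identification (hemisphere level, LH->RH, without ipsilateral)
#>   39/40 correct (success rate 0.975)

permutation_test(edges, direction = "lr", n_iter = 1000, seed = 100)
#> Permutation test: 1000 label shuffles
#>   observed success rate 0.975; max null rate 0.150; p = 0

age_hsfc_correlation(records, cohort$meta, level = "hemisphere")
#> $r        [1] -0.9657522
#> $p        [1] 7.221209e-24
#> $n        [1] 40

group_summary(records[records$level == "hemisphere", ], cohort$meta)
#>         group      level  n      mean         sd
#> Young   Young hemisphere 13 0.6752657 0.05432412
#> Middle Middle hemisphere 13 0.4754056 0.06765106
#> Old       Old hemisphere 14 0.2838283 0.06990512
```

Reading the output: 39 of 40 subjects are identified from the opposite
hemisphere alone, while no random relabelling of the database ever exceeds a
15% success rate, so the empirical p of the observed rate is 0 — hemispheric
similarity patterns are strongly subject-specific. The age–HSFC correlation
is strongly negative and the group means fall from Young to Old, recovering
the asymmetry drift this cohort was generated with.

Demographic comparisons use `chi_square_independence()` (sex by age group,
Pearson chi-square without continuity correction) and `anova_from_summary()`
(one-way F-test reconstructed from per-group mean/SD/n). Robustness to the
parcellation is checked by `derive_coarse_scheme()` +
`cross_template_correlation()`.

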