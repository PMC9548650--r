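Package: hsfc
Title: Hemispheric Similarity of Functional Connectivity and Connectome Fingerprinting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-hemisphere functional connectivity (FC) matrices from
    parcellated ROI time series, computes the hemispheric similarity of
    functional connectivity (HSFC) -- the Pearson correlation between a
    subject's left- and right-hemisphere FC edge vectors -- at hemisphere and
    functional sub-module level, performs cross-hemisphere individual
    identification with a label-shuffle permutation null, and quantifies
    HSFC-age trends and cross-parcellation robustness. A factor-model
    synthetic cohort generator with controllable group, fingerprint and
    asymmetry components makes every pipeline stage testable without
    neuroimaging data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
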