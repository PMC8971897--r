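Package: tremormap
Title: Connectomic Sweet-Spot and Fiber-Filtering Analysis for Dual-Lead
    Thalamic Deep Brain Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for unilateral dual-lead (VIM + VOp) thalamic
    deep brain stimulation of multiple sclerosis tremor. Estimates the
    stimulation electric field and volume of tissue activated (VTA) with an
    analytic point-source model in a homogeneous isotropic medium, maps the
    stimulation sweet spot by improvement-weighted voxel-wise analysis with
    threshold-free cluster enhancement (TFCE) and sign-flip permutation
    family-wise-error inference, computes VTA-seeded structural connectivity
    to cortical regions with regression against tremor improvement, and
    performs discriminative fiber filtering with per-streamline two-sample
    t-scores. Includes a synthetic phantom cohort generator with planted
    ground truth (sweet spot, favorable and unfavorable bundles, outcome
    model) so every stage is testable by parameter recovery, plus NIfTI-1
    and TrackVis TRK input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
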