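Package: phmriVoA
Title: Pharmacological MRI Volume-of-Activation and Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for awake-rodent pharmacological MRI (phMRI)
    dose-response studies. Detects voxel-wise positive and negative BOLD
    signal changes against a pre-injection baseline window, counts
    per-region volumes of activation (VoA) on a labelled brain atlas,
    ranks regions by Kruskal-Wallis dose-group statistics with
    Benjamini-Hochberg false discovery control and omega-squared effect
    sizes, classifies dose-response shapes (inverted-U, U, monotonic),
    and analyses resting-state functional connectivity graphs (degree
    centrality, composite-node coupling). Includes a synthetic cohort
    generator with known ground truth for validation, NIfTI-1 and TSV
    input/output, and a configuration-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
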