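Package: mdslope
Title: Marginal Diffusion Slope Imaging Biomarker for Tumour-Margin Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the marginal diffusion slope (MDS), an imaging
    biomarker of tumour-margin infiltration computed from apparent
    diffusion coefficient (ADC) maps. Builds surface-normal vector fields
    on refined tumour-boundary masks via local eigen-decomposition,
    samples ADC centrifugally across the enhancing margin, fits
    per-profile ordinary least-squares slopes under contiguity and
    FLAIR-abnormality validity rules, and averages them to a patient-level
    biomarker. Includes the validation apparatus: a radial-gradient sphere
    phantom, a Gaussian-cellularity diffusion simulator based on Graham's
    relation, preclinical ADC-versus-cell-density correlation analyses,
    and cohort statistics (Cox proportional hazards per standard
    deviation, Kaplan-Meier summaries, repeated-measures coefficient of
    variation, ICC and Bland-Altman repeatability).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    survival,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'geometry-utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'cohort-stats.R'
    'morphology.R'
    'io.R'
    'surface-vectors.R'
    'profiles.R'
    'preclinical.R'
    'simulation.R'
    'cli.R'
    'mdslope-package.R'
    'synthetic-fixtures.R'
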