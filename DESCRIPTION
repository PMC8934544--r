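Package: zfocular
Title: Zebrafish Ocular Phenotyping from OCT, Photorefraction, Tonometry and
    Optokinetic Assays
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for in vivo ocular phenotyping of
    adult zebrafish across four assays: spectral-domain optical coherence
    tomography (SD-OCT) biometry with per-compartment refractive-index
    correction, eccentric infrared photorefraction with an ophthalmic-lens
    calibration and a Matthiessen-type relative refractive error, rebound
    tonometry aggregation of intraocular pressure readings, and optokinetic
    response quantification (slow-phase velocity, optokinetic gain and eye
    tracking movements per interval). Repeated-measures statistics treat the
    two eyes of a fish as correlated observations through a compound-symmetry
    mixed model fitted by REML, complemented by Welch's ANOVA for per-fish
    metrics, a body-length matching filter and Monte-Carlo power estimation.
    A seeded synthetic model-eye generator renders all four raw-data streams
    (OCT volumes, pupil frames, eye-angle traces, tonometer readings) from
    parameterized eye geometries so the full pipeline can be validated by
    round-trip simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    nlme,
    tiff,
    png,
    jsonlite,
    yaml,
    signal,
    pracma,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Software, Visualization, Preprocessing
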