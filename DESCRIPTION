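Package: stimtract
Title: Connectomic Overlay Analysis of Deep Brain Stimulation Electrodes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Links deep-brain-stimulation electrode positions to clinical
    improvement through normative tractography. Models the volume of
    activated tissue (VAT) around electrode contacts as a sphere whose
    radius follows from a Coulomb-law field model, rasterizes streamline
    bundles to smoothed density images, scores bundle activation as the
    mean density inside each VAT, regresses outcome improvement on
    activation with leave-one-out validation, selects streamlines from a
    normative connectome by spherical ROIs, and detects cortical
    terminal-density peaks and conjugation (overlap) regions between
    stimulation targets. Includes a synthetic-data generator producing
    fiber bundles, bilateral electrode cohorts and outcomes with the
    statistical structure the analysis assumes, so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
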