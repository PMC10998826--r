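Package: LuDosim
Title: Image-Based Internal Dosimetry and Blood Stability Analysis for
    Lu-177 Peptide Receptor Radionuclide Therapy Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative-SPECT internal dosimetry of Lu-177
    labelled radioligands: a synthetic multi-time-point phantom generator
    with known regional kinetics, threshold volume-of-interest tumor
    activity estimation with background correction, mono-exponential
    time-activity-curve fitting with effective half-life estimation and
    time-integrated disintegration counts (closed form or trapezoid with
    physical-decay tail), a simplified Monte-Carlo voxel energy-deposition
    kernel for Lu-177 point sources in soft tissue, absorbed-dose
    calculation for tumors and organs (Gy and Gy/GBq), radio-HPLC
    percent-intact-peptide quantification from chromatograms, and exact
    paired Wilcoxon signed-rank statistics for premedication cross-over
    comparisons. Ships transcribed per-patient stability and dose tables
    from a first-in-human minigastrin premedication study as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'nucdata.R'
    'nifti.R'
    'phantom.R'
    'voi.R'
    'kinetics.R'
    'dose.R'
    'stability.R'
    'stats.R'
    'fixtures.R'
    'report.R'
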