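Package: msgrad
Title: Scan-Driven Optimization of LC-MS/MS Solvent Gradients
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes optimized non-linear reversed-phase LC gradients for
    LC-MS/MS acquisitions from MS/MS scan metadata alone. Retention times of
    high total-ion-current MS/MS scans acquired on a standard (typically
    linear) gradient are mapped to the percent solvent B at which each
    precursor eluted, and a stepped piecewise-linear gradient is constructed
    whose steps each bracket an equal fraction of those scans, spreading
    peptide elution evenly across the analytical window. Includes mzML scan
    metadata import, delay-aware retention-time/composition mapping,
    redistribution diagnostics (Kolmogorov-Smirnov uniformity), a seeded
    synthetic-run generator for validation, and exporters for LC control
    software. No peak picking or peptide identifications are required.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports: methods, stats, utils, jsonlite, mzR
Suggests: testthat (>= 3.0.0), optparse, withr
biocViews: Proteomics, MassSpectrometry, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
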