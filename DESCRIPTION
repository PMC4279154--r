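Package: willowNMR
Title: High-Throughput 1D 1H-NMR Metabotyping of Biomass Willow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A simulation-backed pipeline for 600-MHz 1D 1H-NMR metabotyping
    of willow (Salix) leaf and stem polar extracts. Provides a metabolite
    signature library (multiplet centres, J couplings, proton counts),
    a frequency-domain spectrum simulator reproducing the matrix artifacts of
    buffered deuterated plant extracts (pH shifts, Ca2+ peak broadening,
    Ca-EDTA complex peaks, catechin H/D exchange), spectral preprocessing
    (TSP referencing, 0.015-ppm bucketing, internal-standard scaling),
    targeted metabolite quantification by bounded-shift Lorentzian
    least-squares fitting, extractable-pool normalisation and replicate
    statistics, and PCA/OPLS fingerprint mining with S-line outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    pracma,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
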