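Package: diadirect
Title: Direct Database Searching of Data-Independent Acquisition Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A self-contained, testable search engine for data-independent
    acquisition (DIA) proteomics. DIA MS/MS spectra are searched directly
    against a protein sequence database using a fragment-ion index, before
    any feature detection: precursor mass bounds are enumerated from the
    isolation window, candidates are ranked per spectrum, and matches are
    refined by targeted extracted-ion-chromatogram (XIC) tracing with a
    median apex retention-time filter and an averagine isotope-envelope
    check. Spectra are deconvolved by greedy iterative hyperscore rescoring
    with matched-peak removal. Confidence estimation uses target-decoy
    q-values with multi-level (run/global, precursor/protein) filtering,
    plus spike-in and entrapment false-discovery-proportion estimators.
    A deterministic DIA run simulator with full ground truth supports
    benchmarking, and writers are provided for mzML, pepXML, Percolator
    input (pin) and tab-separated spectral libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    xml2,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
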