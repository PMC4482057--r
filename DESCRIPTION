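Package: idaa
Title: Indel Detection by Amplicon Analysis from Capillary Electrophoresis Traces
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computational readout for Indel Detection by Amplicon Analysis
    (IDAA): reads ABIF (.fsa) fragment-analysis traces of fluorescently
    labelled amplicons, detects and integrates electropherogram peaks,
    calibrates scan coordinates to fragment sizes against an in-lane size
    standard (Local Southern sizing), calls signed integer indel alleles at
    1-bp resolution with peak-area allele fractions and nuclease cutting
    efficiencies, genotypes single-cell clones for frame-disrupting indels,
    supports tri-primer assay design (expected labelled-amplicon size,
    PAM-adjacent off-target candidate enumeration), and simulates
    multi-channel electropherograms so the whole pipeline is testable
    without an instrument.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'abif-io.R'
    'trace-processing.R'
    'size-standards.R'
    'ladder-calibration.R'
    'indel-calling.R'
    'assay-design.R'
    'simulator.R'
    'pipeline.R'
    'report.R'
    'idaa-package.R'
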