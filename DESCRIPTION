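Package: sumiseq
Title: Simulation and Processing of UMI-Barcoded DNA Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for secondary-structure-assisted UMI amplicon sequencing
    (sUMI-seq) of DNA templates: a generative simulator of the two-stage
    barcoded PCR (near-linear UMI-tagging PCR followed by exponential
    amplification with per-molecule efficiency bias and per-base sequencing
    error), paired-read quality filtering and exact-overlap merging, primer
    and UMI identification, UMI-group consensus calling for sequencing-error
    and amplification-bias correction, amplification-bias and loop
    re-amplification statistics, and B-cell receptor repertoire analytics
    (germline annotation, Hamming-1 clone networks, Renyi clonal
    diversification, intraclonal diversity and somatic hypermutation
    summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
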