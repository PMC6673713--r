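Package: nucfoot
Title: Single-Molecule Nucleosome Footprinting from Nanopore Methylation Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls GpC 5-methylcytosine from nanopore event-level signal using
    per-6-mer Gaussian (unmethylated) and two-component Gaussian-mixture
    (methylated) models, phases nucleosomes along single long reads with a
    constrained 148-state dynamic-programming decoder over kernel-density
    score emissions, derives single-molecule and bulk chromatin-accessibility
    calls (accessible regions, peaks, promoter open/closed status), computes
    downstream heterogeneity statistics (+1-nucleosome positioning spread,
    nucleosome spacing uniformity, combinatorial promoter patterns,
    score-distance correlograms, openness clustering), and ships a simulation
    framework with ground-truth occupancy labels for evaluating decoder
    accuracy across nucleosome coverage and GpC frequency.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    data.table,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    mclust,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
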