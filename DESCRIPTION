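Package: infoprofile
Title: Information Profiles of DNA Sequences from Adaptive Mixtures of
    Finite-Context Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes per-base "information profiles" of DNA sequences: the
    local information content -log2 P(base) under an adaptive mixture of
    order-k finite-context (Markov) models whose weights track each model's
    recent predictive performance through an exponential forgetting factor.
    Sequences are processed in the direct and reversed directions and the
    per-position minimum is taken to remove directional bias; profiles are
    low-pass filtered with a Blackman window, subsampled, and exported as
    WIG, bedGraph or TSV genome-browser tracks. Conditional profiles (models
    trained on a reference sequence, applied with frozen statistics to a
    target) localize divergence between assemblies. Includes a synthetic
    sequence generator with planted repeats for validation, plotting helpers
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    BiocGenerics,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
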