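Package: dentplan
Title: Rule-Based and Neural Planning of Dental Prostheses on Synthetic
    Findings Charts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying machine-learned dental prosthesis planning
    on a single 16-tooth jaw. Provides a deterministic standard-care rule
    engine that maps a findings chart (ten finding codes per tooth) to a
    treatment plan (no treatment, crown, bridge unit, or removable
    denture per tooth), a constrained generator of valid synthetic
    labelled case collections, a compact sequence-labelling neural
    network engine (token embedding, bidirectional LSTM, dropout,
    position-wise dense layers, softmax output) with a reproducible
    training protocol (Adam, learning-rate plateau halving, early
    stopping with best-weight restore), and experiment drivers for
    learning curves and architecture comparisons with Kruskal-Wallis and
    Dunn-Bonferroni statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: C++17
NeedsCompilation: yes
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
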