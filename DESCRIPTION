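Package: esabo
Title: Entropy Shifts of Abundance Vectors under Boolean Operations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers signed (synergistic and competitive) microbial
    interaction networks from binarized presence/absence abundance tables
    using the ESABO statistic: the Shannon entropy of the elementwise
    Boolean combination of two abundance vectors, z-scored against a
    permutation null.  Includes a signed Boolean network simulator whose
    attractor states serve as synthetic steady-state community
    compositions for calibrating and benchmarking the method, closed-form
    pair-count algebra for all informative two-input Boolean operations,
    binomial co-occurrence z-scores and binary Jaccard indices, ensemble
    benchmarks over connectivity and noise, and utilities for reading and
    writing abundance tables and signed edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
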