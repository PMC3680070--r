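Package: ppidiag
Title: Instance-Level Difficulty and Agreement Diagnostics for Relation
    Extraction Benchmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for instance-level error analysis of binary relation
    extraction systems, developed around protein-protein interaction (PPI)
    benchmark corpora. Reads the unified PPI corpus XML interchange format
    and flat prediction tables, computes per-pair classification success
    levels across a roster of classifiers, stratifies candidate pairs into
    difficult/neutral/easy classes with chi-square overlap tests, reports
    observed versus expected correctness per stratum, clusters classifiers
    by instance-level prediction agreement with Newick dendrogram export,
    extracts surface and parse features with information-gain ranking,
    predicts pair difficulty with decision trees, and evaluates
    majority-vote ensembles. Includes a seeded synthetic-corpus and
    prediction-matrix generator emulating the statistical structure of the
    five standard PPI benchmarks so the full pipeline is testable without
    the original corpora or classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    xml2,
    igraph,
    ape,
    jsonlite,
    yaml,
    rpart,
    e1071,
    class,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
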