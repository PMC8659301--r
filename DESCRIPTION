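Package: domainmapr
Title: Statistical Mapping of Small-Molecule Compounds to Protein Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maps small-molecule compounds to protein domains and unordered
    domain pairs from labeled bioactivity data. Compound-target activity
    records (xC50-type values in micromolar) are classified into active and
    inactive pairs, duplicates are collapsed by median, and each eligible
    compound (or Tanimoto-similarity compound cluster) is scored against the
    domains of its targets with confusion-matrix metrics (recall, precision,
    accuracy, F1, Matthews correlation coefficient), optionally substituting
    domains from the same InterPro-style hierarchy. Filtered mappings are
    propagated to all proteins carrying the mapped domain feature and to
    structurally similar compounds (ECFP4 fingerprints, Tanimoto coefficient)
    to yield drug/compound-target interaction predictions, which can be
    grouped by pathway. Mapping sets are evaluated against a reference set
    with coverage, coverage-extension, and hypergeometric enrichment
    statistics. A deterministic synthetic-world generator with planted
    ground-truth associations supports end-to-end testing without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    ChemmineR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
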