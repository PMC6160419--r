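Package: netmod
Title: Disease Network Module Detection on Confidence-Weighted Interactomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds disease network modules on confidence-weighted
    protein-protein interaction networks. Genes around disease seed genes
    are ranked by a degree-adjusted random walk with restart, the
    neighborhood boundary is chosen from gene-level association p-values,
    external candidate genes (for example pull-down interactors) are scored
    for network proximity with a confidence-weighted closeness Z-score, a
    single connected module is assembled with a greedy Steiner strategy,
    and the module is validated against differential-expression tables.
    A synthetic-data generator produces interactomes with planted modules
    so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'interactome-io.R'
    'neighborhood.R'
    'cab.R'
    'local-radiality.R'
    'steiner.R'
    'validation.R'
    'simulate.R'
    'pipeline.R'
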