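Package: chromafactor
Title: Deconvolution of Single-Molecule Chromatin Conformation Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes heterogeneous single-molecule chromatin conformation
    datasets (stacks of per-cell pairwise distance matrices from chromatin
    tracing or single-cell Hi-C) into non-negative template matrices and
    per-cell weights using non-negative matrix factorization, selects the
    number of components with a multi-metric framework, links components to
    matched transcription labels by nonparametric testing and balanced
    random-forest classification, and extracts the cell subpopulations that
    drive bulk contact trends. Includes quality-control filtering, linear
    imputation and max-normalization for coordinate tables, insulation and
    directionality-index tracks with boundary calling, protein-peak
    colocalization, and a ground-truthed synthetic-data generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    digest,
    clue,
    uwot,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
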