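Package: leverageCUR
Title: CUR Matrix Decomposition and Leverage-Score Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for CUR matrix decompositions of dense numeric matrices,
    built on normalized statistical leverage scores computed from the top-k
    singular vectors. Provides five column/row selection strategies (the
    randomized ColumnSelect sampler, an exact-count weighted sampler, and
    three deterministic score-based strategies), assembly of the C, U and R
    factors (including the restricted one-sided form A ~ C X) with
    relative approximation-error diagnostics, leverage-based feature
    selection for gene-expression matrices, PCA sample scores, a
    group-separation statistic for assessing class discrimination in
    reduced feature sets, and seeded synthetic-matrix generators for
    low-rank-plus-noise and grouped-expression designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics
Suggests: testthat (>= 3.0.0), MASS, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'leverage.R'
    'selection.R'
    'decomposition.R'
    'analysis.R'
    'synthetic.R'
    'io.R'
    'cli.R'
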