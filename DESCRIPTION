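Package: CNAcooccur
Title: Genome-Wide Co-Occurrence Scoring of DNA Copy Number Alterations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores every pair of genomic loci for concerted DNA copy number
    gain and loss across a tumor panel. Probe-level log2 ratios are
    interpolated onto an equally spaced genomic grid, split into non-negative
    gain and loss channels, and each pair of chromosome-arm grid points is
    scored with a summed pairwise minimum weighted by the across-sample
    covariance. Score matrices are smoothed by multi-scale isotropic 2D
    Gaussian convolution with mirror padding, and ranked peak lists of
    co-occurring locus pairs are extracted. Downstream tools annotate peaks
    with gene sets, test cancer-gene-category and functional-interaction
    enrichment against random-locus controls, and assemble co-occurrence
    networks with single-linkage locus clustering and core-network pruning.
    A simulation module generates probe-level datasets with planted lesions,
    including a two-lineage co-deletion scenario, for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    methods,
    data.table,
    igraph,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
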