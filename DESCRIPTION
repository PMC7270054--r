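Package: connectopy
Title: Connectopic Mapping of Tractography Connectivity Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes overlapping connectivity gradients ("connectopic maps")
    from probabilistic-tractography seed-by-target visitation count matrices.
    Connectivity profiles are compared with the eta-squared similarity
    coefficient, embedded with Laplacian eigenmaps on a minimally connected
    k-nearest-neighbour graph, and normalised to the 1-10 gradient scale.
    Includes maximum-likelihood intrinsic dimensionality estimation,
    white-matter projection images and per-tract summaries, ICC(2,1)
    test-retest reliability with bootstrap confidence intervals, decile-based
    functional decoding against a term-map library, and a synthetic-cohort
    generator with planted gradient ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    RNifti,
    yaml,
    xml2,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
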