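Package: cpddm
Title: Robust Kernel Domain Adaptation via Possibilistic Distribution Distance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised domain adaptation for numeric feature tables that is
    robust to outliers and label noise. The maximum mean discrepancy (MMD)
    between a labeled source domain and an unlabeled target domain is relaxed
    to a possibilistic one-cluster-center objective in kernel space: each
    sample receives a membership weight that decays exponentially with its
    squared RKHS distance to blended whole-domain and class-conditional means,
    with a fuzzy-entropy regularizer to avoid the trivial all-zero solution.
    The memberships are optimized jointly with a graph-Laplacian label
    propagation term and an l2,1-regularized least-squares classifier by
    alternating closed-form updates; target labels are inferred by a spectral
    trace minimization and a fused source/target linear classifier. Includes a
    seeded synthetic two-domain generator (Gaussian class clusters, covariate
    shift, far outliers, flipped source labels) and delimited-text readers and
    writers, plus a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
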