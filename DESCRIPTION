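Package: mdcl
Title: Mutual Distillation Objectives for Class-Incremental Continual Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for class-incremental continual learning of image
    classifiers with a mutual distillation objective. The combined continual
    loss couples an acquisition term (KL divergence against new labels), a
    retention term (cross-entropy against a frozen teacher's soft outputs),
    and a mutual distillation term built from Bayes posteriors of
    class-conditional multivariate Gaussian models fitted to the joint
    old/new soft representations of each sample. Includes a small reference
    network trained with ADADELTA, teacher snapshotting, exemplar memory,
    a synthetic multi-domain shape benchmark (grayscale and colour domains,
    composite "multiple" class, configurable class imbalance), standard
    classification metrics, per-increment forgetting curves, intra-domain
    transferability grids, temperature sweeps, and loss-variant comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
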