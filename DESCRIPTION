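Package: ampgraph
Title: Adversarial Multimodal Patient-Graph Learning for Diagnostic Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multimodal patient-network diagnosis from per-modality feature
    tables. Per-modality feature extractors are aligned in a common embedding
    space by an adversarially trained modality discriminator with an
    invert-label loss; a learnable cosine-similarity patient graph is inferred
    per modality, fused by learned simplex weights into one global adjacency,
    and node labels are predicted transductively by Simple Spectral Graph
    Convolution (S2GC) with a linear head. Includes a synthetic multimodal
    cohort generator with planted class structure and modality shifts,
    stratified cross-validated evaluation (ACC/AUC/SEN/SPE), ablation and
    modality-combination runners, silhouette diagnostics, and tidy/broom-style
    accessors with ggplot2 plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    cluster,
    nnet,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC
Config/testthat/edition: 3
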