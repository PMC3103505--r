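Package: netdiscrim
Title: Weighted Brain Network Construction, Metrics and Group Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds weighted structural brain connectomes from deterministic
    diffusion-tensor fiber tracking, extracts maximum-spanning-tree
    connectivity backbones, computes six weighted graph measures (clustering,
    characteristic path length, modularity, global and local efficiency, and
    small-worldness against a degree-preserving null ensemble), embeds
    subjects in per-measure representation spaces, classifies groups by
    leave-one-out linear discriminant analysis with forward sequential
    feature selection, and compares groups with a max-t permutation test.
    Includes a synthetic-data generator emulating a two-group dysmyelination
    study design so the full pipeline can be exercised and validated without
    imaging data.
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
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    RNifti,
    testthat (>= 3.0.0)
LinkingTo:
    Rcpp
Config/testthat/edition: 3
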