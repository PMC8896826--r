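Package: orthosample
Title: Phylogeny-Guided Selection of Representative Orthologs and
    Phenotype-Distance Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting a representative subset of orthologs from a
    maximum-likelihood phylogeny and relating a binary experimental phenotype
    to phylogenetic distance from a focal (host) ortholog. Implements
    patristic-distance computation on Newick trees, TreeCluster-style
    threshold clustering (max and max-clade modes), hierarchical subclustering
    with one-representative-per-subcluster selection under user priorities,
    Wilcoxon rank-sum validation that a selected subset is representative of
    the full ortholog set, the correlation ratio (eta) between a categorical
    outcome and patristic distance, structured complementation-screen tables
    with their headline counts, and Yule-tree / binary-trait simulators for
    calibration. Results are tibbles with broom-style tidy() and glance()
    methods and ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
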