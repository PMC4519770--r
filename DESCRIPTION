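Package: editnet
Title: RNA Editing Quantification and Network Analysis for the 5-HT2C
    Receptor Editing System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying adenosine-to-inosine (A-to-I) RNA editing
    of the serotonin 2C receptor (5-HT2CR) and its regulation by ADAR2
    (Adarb1). Quantifies the 32 combinatorial editing variants and 24
    receptor isoforms from amplicon sequencing reads, computes per-site
    editing efficiencies, estimates Kv1.1 (Kcna1) editing from MfeI
    restriction-digest fragment profiles, performs differential
    expression with fold-change and FDR thresholds, builds
    editing/Adarb1 trait signatures with Spearman correlation and Fisher
    exact overlap tests, detects weighted co-expression modules via
    topological overlap, and classifies every gene as upstream,
    downstream, independent or ambiguous relative to Adarb1 by scoring
    the twelve admissible three-node Bayesian networks over treatment,
    gene and Adarb1. A synthetic-data module generates amplicon reads,
    negative-binomial expression studies with planted causal structure,
    and digest mixtures so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
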