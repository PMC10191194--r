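Package: mycoflux
Title: Quantifying Host-Derived Carbon Acquisition by Ectomycorrhizal Fungi
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the carbon that ectomycorrhizal fungi
    acquire from their plant host in 13CO2 pulse-labelling microcosm
    experiments, and for relating that carbon flux to fungal growth traits
    and to plant and fungal gene expression. Implements the two-pool
    stable-isotope mixing model converting 13C atom percent measurements of
    extra-radical mycelium, free-living mycelium, and leaves into percentage
    and absolute amounts of host-derived carbon (with interquartile-range
    outlier filtering); derivation of fungal growth traits (colonization
    rate, hyphal density, radial growth rate) with ANOVA, Tukey HSD compact
    letter displays, PCA, and trait-carbon correlations; and a transcriptome
    screen that filters expressed transcripts, normalizes counts by the
    median-of-ratios estimator, builds log2 fold-change matrices with
    hierarchical clustering, and selects the top and bottom percentiles of
    per-transcript Pearson correlations with carbon acquisition. A synthetic
    data generator with known ground truth supports validation of every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    DESeq2,
    multcomp,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
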