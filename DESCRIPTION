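Package: baitprey
Title: Bait-Prey Interactome Construction from AP-MS Spectral Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for building a protein interactome
    from affinity-purification mass-spectrometry (AP-MS) spectral counts.
    Provides fold-enrichment and NSAF normalisation of bait versus control
    counts, a simplified SAINT-style Poisson mixture posterior (MaxP) score,
    two-pass candidate filtering with literature/family/multi-experiment
    rescue, CRAPome-style contaminant removal, Platinum/Gold/Silver/Bronze
    confidence tiering, synapse-proteome and developmental partitioning,
    protein-network summary statistics, current-voltage (IV) reversal-potential
    regression, and pooled two-sample t tests recomputed from printed group
    summaries. Ships the printed table of KCC2 multi-epitope AP partners as a
    plain-text fixture and a seeded synthetic AP-MS generator so the whole
    pipeline is testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
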