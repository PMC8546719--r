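Package: vhocnet
Title: Virus-Host Prediction from Co-Occurrence Networks with
    Phylogeny-Guided Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers and assesses virus-host associations between giant
    viruses (NCLDVs, tracked by their polB marker gene) and marine
    eukaryotes (18S V9 metabarcodes) from paired abundance tables.
    Provides centered log-ratio preprocessing with quartile-based
    low-abundance filtering, signed Spearman co-occurrence networks with
    optional environmental conditioning, a positive-likelihood-ratio
    (LR+) and false-discovery-rate validation framework against known
    virus-host references, a phylogeny-guided enrichment filter (Taxon
    Interaction Mapper) over a viral marker-gene tree, virophage-NCLDV
    clade enrichment and HGT-candidate screening, and a synthetic
    community generator with planted, phylogenetically structured
    virus-host couplings for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    ape,
    phangorn,
    vegan,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
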