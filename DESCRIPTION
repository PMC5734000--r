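Package: careflow
Title: Clinical Pathway Spectra and Correlation-Network Clustering of Care Providers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining clinical care pathways from time-stamped,
    per-patient administrative claims events. Extracts gap-delimited care
    episodes ("event series"), classifies each into one of 15 pathway types
    by the order of first occurrence of non-invasive non-imaging (E),
    non-invasive imaging (NI) and invasive (I) procedures, assigns de facto
    care centers to ZIP areas by majority vote, characterizes centers by
    their 15-component pathway spectra, builds a Pearson-correlation network
    of centers, clusters it by native Louvain modularity optimization
    (hierarchically, up to three levels), and summarizes clusters by cost,
    revascularization rate and 365-day mortality with Fisher exact tests and
    direct standardization. A synthetic reimbursement-registry generator with
    planted regional practice archetypes makes every stage testable without
    access to real claims data.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
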