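Package: mycodiv
Title: Diversity and Distribution Analysis of Culturable Endophyte Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing culturable endophytic fungal surveys laid out
    as species-by-(season, site, tissue) colonization-frequency matrices.
    Provides readers and reshapers for percent colonization-frequency tables,
    the standard alpha-diversity index suite (species richness, Gleason and
    relative Gleason, Simpson dominance and its complement, Shannon-Wiener
    entropy, Pielou evenness), presence/absence Jaccard similarity between
    sampling sites, a balanced three-way factorial analysis of variance
    computed from sums-of-squares first principles, a generative simulator of
    segment-level fungal colonization with the survey's factorial design, and
    summaries of antibacterial screening tables (active fraction, MIC range).
    All results are returned as tibbles and plotable with ggplot2.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
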