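Package: algalipids
Title: Lipidomics, Nutritional Quality Indices and Bioactivity Assays for
    Microalgal Lipid Extracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing microalgal lipid profiles across strains:
    parsing of fatty-acid and lipid-species shorthand, internal-standard
    normalization of GC-MS fatty-acid and LC-MS lipidomics peak tables,
    relative-abundance profiles with saturation-class and omega-family sums,
    lipid nutritional quality indices (atherogenic, thrombogenic,
    hypocholesterolemic/hypercholesterolemic ratio, peroxidation index,
    n-6/n-3 ratio), dose-response analysis of radical-scavenging and COX-2
    inhibition assays (ICx by interpolation, Trolox equivalents), and a
    multi-group feature-comparison workflow (normality/homoscedasticity
    gating, ANOVA/Tukey or Kruskal-Wallis/Dunn, Benjamini-Hochberg q-values,
    PCA, Ward hierarchical clustering). Includes a seeded synthetic-data
    generator that emulates a four-strain Chlorella vulgaris study design
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    car,
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
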