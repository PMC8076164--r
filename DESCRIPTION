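Package: hebelomaGL
Title: Morphometrics, Identification Keys and Biogeography for Greenland Hebeloma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the taxonomy of the ectomycorrhizal genus Hebeloma
    (Hymenogastraceae) in Greenland. Implements the standard spore and
    cheilocystidium measurement protocol (per-collection summaries with
    medians, standard deviations and 5/95 percentiles, Q values and A/M,
    A/B, B/M cystidium ratios), ordinal spore-trait coding (O/P/D scales),
    a three-valued dichotomous key engine covering the section key and the
    species keys for sections Hebeloma, Denudata and Velutipes, a
    machine-readable trait database for the 28 Greenland species, the
    378-collection occurrence catalogue with region, bioclimatic-zone and
    distribution-group tabulation, ITS variant collapsing with pairwise
    distance and shared-variant tables, and a seeded synthetic-specimen
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
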