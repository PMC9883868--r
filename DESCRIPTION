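Package: endodiv
Title: Diversity and Bioactivity Analysis of Culturable Endophyte Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing culture-dependent surveys of endophytic
    fungi. Tabulates genus-level abundances per plant tissue from an isolate
    catalog, computes six alpha-diversity indices (Margalef, Shannon-Wiener,
    Simpson diversity and dominance, probability of interspecific encounter,
    Pielou evenness), builds neighbor-joining ITS phylogenies with bootstrap
    support from scratch, and summarises seed-germination phytotoxicity and
    disc-diffusion antibacterial screens with activity banding and the
    associated ANOVA/LSD and t statistics. Ships the isolate, phytotoxicity
    and antibacterial tables of a Pinellia ternata / Pinellia pedatisecta
    survey as fixtures, plus seeded generators for synthetic catalogs,
    bioassays and alignments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
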