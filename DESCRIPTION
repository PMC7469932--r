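Package: capsforge
Title: CAPS Marker Design and S-RNase Allele Genotyping for Prunus
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing Cleaved Amplified Polymorphic Sequence
    (CAPS, PCR-RFLP) marker systems and for genotyping S-RNase alleles of
    gametophytically self-incompatible Prunus species. Provides in-silico
    amplification with degenerate primers, complete restriction digestion
    with a gel-observation model, search for minimal discriminating enzyme
    panels, composite-fingerprint guide construction, band-based allele and
    genotype calling with novel-allele designation, classification of
    crosses under gametophytic self-incompatibility, and alignment
    variability statistics (per-column Shannon entropy and Nei-Gojobori
    Ka/Ks with a sliding window) used to choose assay target regions.
    Ships a machine-readable reference guide for Andean capuli
    (Prunus serotina subsp. capuli) S-RNase alleles and a seeded synthetic
    allele-panel generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
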