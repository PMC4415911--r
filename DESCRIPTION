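Package: hcscreen
Title: Germline Variant Prioritization and Microsatellite Instability
    Calling for Hereditary Cancer Gene Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Prioritizes germline variants from annotated hereditary-cancer
    gene-panel screens. Parses cDNA and protein HGVS nomenclature into
    consequence classes (frameshift and in-frame indels, nonsense, missense,
    splice-site), applies call-level quality filters and a four-criterion
    candidate filter cascade (region, consequence class, population allele
    frequency, inheritance-mode consistency with a recessive single-candidate
    clause), and assigns deleteriousness with a two-feature in-silico missense
    rule (prediction software plus evolutionary conservation) gated on manual
    curation evidence. Also scores variant segregation in pedigrees, evaluates
    family-history eligibility rules, classifies microsatellite instability
    (MSI) and elevated microsatellite alterations at selected tetranucleotide
    repeats (EMAST) from marker-panel stability calls, scores
    immunohistochemistry staining change, and aggregates per-proband calls into
    cohort summaries. A seeded synthetic-cohort generator produces pedigrees,
    background polymorphism tables with spiked pathogenic variants, and
    mismatch-repair-conditioned marker profiles so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
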