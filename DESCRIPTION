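Package: suspectms
Title: Suspect Screening of Xenobiotic Metabolites in LC-HRMS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Rule-based suspect screening for xenobiotic biotransformation
    products in liquid chromatography high-resolution mass spectrometry
    (LC-HRMS) feature data. Enumerates phase I / phase II candidate
    metabolites from a parent compound and a configurable biotransformation
    rule set, matches observed features by exact monoisotopic mass within a
    ppm tolerance, corroborates annotations with simulated isotope patterns
    and conjugate-class diagnostic fragments in MS/MS spectra, excludes
    features present in non-exposed control groups, and profiles
    creatinine-normalized metabolite abundances across dose groups to
    detect metabolic switching. Ships a curated reference set of limonene
    metabolites and a seeded synthetic-cohort generator so the whole
    pipeline is testable without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
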