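Package: raceaudit
Title: Conformance Auditing of Race and Ethnicity Data in Multi-Site Clinical Extracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Harmonizes heterogeneous source encodings of patient race and
    ethnicity to the OMB 1997 / HL7 minimum categories, classifies every
    record as conforming or into a seven-way nonconformance taxonomy
    (missing, other, refused, multiracial, misclassified, uninterpretable,
    more granular), and tabulates weighted audit reports by harmonized
    concept, ethnicity, site reporting schema, and common data model
    (OMOP, PCORnet, ACT, TriNetX, PEDSnet). Includes a seedable multi-site
    synthetic cohort generator with ground-truth mechanism labels and a
    deterministic weighted fixture encoding the published data-quality
    marginals of the National COVID Cohort Collaborative (N3C) enclave.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
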