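# Concept registry: OMB 1997 / HL7 minimum race and ethnicity categories,
# the granular roll-up children observed in multi-site EHR feeds, and the
# flag concepts used by harmonization pipelines for non-standard values.
# axis: RACE / ETHNICITY / ANY (flags apply to either axis).
version: 1
concepts:
  # ---- main race categories (OMB 1997, HL7 codes) ----
  - {concept_id: AIAN,        display: "American Indian or Alaska Native",            axis: RACE, level: MAIN, hl7_code: "1002-5"}
  - {concept_id: ASIAN,       display: "Asian",                                       axis: RACE, level: MAIN, hl7_code: "2028-9"}
  - {concept_id: BLACK_AA,    display: "Black or African American",                   axis: RACE, level: MAIN, hl7_code: "2054-5"}
  - {concept_id: NHPI,        display: "Native Hawaiian or Other Pacific Islander",   axis: RACE, level: MAIN, hl7_code: "2076-8"}
  - {concept_id: WHITE,       display: "White",                                       axis: RACE, level: MAIN, hl7_code: "2106-3"}
  # ---- main ethnicity categories ----
  - {concept_id: HISPANIC,     display: "Hispanic or Latino",     axis: ETHNICITY, level: MAIN, hl7_code: "2135-2"}
  - {concept_id: NOT_HISPANIC, display: "Not Hispanic or Latino", axis: ETHNICITY, level: MAIN, hl7_code: "2186-5"}
  # ---- granular race categories seen in source feeds ----
  - {concept_id: ASIAN_INDIAN,       display: "Asian Indian",          axis: RACE, level: GRANULAR, parent: ASIAN}
  - {concept_id: FILIPINO,           display: "Filipino",              axis: RACE, level: GRANULAR, parent: ASIAN}
  - {concept_id: CHINESE,            display: "Chinese",               axis: RACE, level: GRANULAR, parent: ASIAN}
  - {concept_id: KOREAN,             display: "Korean",                axis: RACE, level: GRANULAR, parent: ASIAN}
  - {concept_id: VIETNAMESE,         display: "Vietnamese",            axis: RACE, level: GRANULAR, parent: ASIAN}
  - {concept_id: JAPANESE,           display: "Japanese",              axis: RACE, level: GRANULAR, parent: ASIAN}
  - {concept_id: GUAMANIAN_CHAMORRO, display: "Guamanian or Chamorro", axis: RACE, level: GRANULAR, parent: NHPI}
  - {concept_id: POLYNESIAN,         display: "Polynesian",            axis: RACE, level: GRANULAR, parent: NHPI}
  - {concept_id: JEWISH,             display: "Jewish",                axis: RACE, level: GRANULAR, parent: WHITE}
  # ---- granular ethnicity categories ----
  - {concept_id: PUERTO_RICAN,     display: "Puerto Rican",     axis: ETHNICITY, level: GRANULAR, parent: HISPANIC}
  - {concept_id: MEXICAN,          display: "Mexican",          axis: ETHNICITY, level: GRANULAR, parent: HISPANIC}
  - {concept_id: CUBAN,            display: "Cuban",            axis: ETHNICITY, level: GRANULAR, parent: HISPANIC}
  - {concept_id: SOUTH_AMERICAN,   display: "South American",   axis: ETHNICITY, level: GRANULAR, parent: HISPANIC}
  - {concept_id: CENTRAL_AMERICAN, display: "Central American", axis: ETHNICITY, level: GRANULAR, parent: HISPANIC}
  - {concept_id: DOMINICAN,        display: "Dominican",        axis: ETHNICITY, level: GRANULAR, parent: HISPANIC}
  - {concept_id: SPANIARD,         display: "Spaniard",         axis: ETHNICITY, level: GRANULAR, parent: HISPANIC}
  # ---- flag concepts (no parent; either axis) ----
  - {concept_id: NO_MATCHING_CONCEPT, display: "No matching concept", axis: ANY, level: FLAG}
  - {concept_id: OTHER,               display: "Other",               axis: ANY, level: FLAG}
  - {concept_id: OTHER_RACE,          display: "Other race",          axis: ANY, level: FLAG}
  - {concept_id: REFUSED,             display: "Refused",             axis: ANY, level: FLAG}
  - {concept_id: UNKNOWN,             display: "Unknown",             axis: ANY, level: FLAG}
  - {concept_id: NO_INFORMATION,      display: "No information",      axis: ANY, level: FLAG}
  - {concept_id: NULL_VALUE,          display: "Null",                axis: ANY, level: FLAG}
  - {concept_id: MISSING_SENTINEL,    display: "Missing",             axis: ANY, level: FLAG}
  - {concept_id: MULTIPLE_RACE,       display: "Multiple race",       axis: ANY, level: FLAG}
  - {concept_id: BLACK_UNMAPPED,      display: "Black",               axis: ANY, level: FLAG}
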