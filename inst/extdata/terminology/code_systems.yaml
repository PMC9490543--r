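# Per-dialect code tables: normalized source value -> concept_id.
# One system per common-data-model dialect plus generic CDC/HL7 code tables
# and a free-text LOCAL dialect for site-specific labels.  Lookup keys are
# matched after case-folding, trimming and whitespace collapsing.
version: 1
systems:
  - system_id: CDC_RACE
    data_model: LOCAL
    entries:
      "2106-3": WHITE
      "2054-5": BLACK_AA
      "2028-9": ASIAN
      "2076-8": NHPI
      "1002-5": AIAN
      "2131-1": OTHER_RACE
      "white": WHITE
      "black": BLACK_AA
      "asian": ASIAN
      "hispanic": HISPANIC
  - system_id: CDC_ETH
    data_model: LOCAL
    entries:
      "2135-2": HISPANIC
      "2186-5": NOT_HISPANIC
      "hispanic or latino": HISPANIC
      "not hispanic or latino": NOT_HISPANIC
      "unknown": UNKNOWN
  - system_id: PCORNET_RACE
    data_model: PCORNET
    entries:
      "01": AIAN
      "02": ASIAN
      "03": BLACK_AA
      "04": NHPI
      "05": WHITE
      "06": MULTIPLE_RACE
      "07": REFUSED
      "ni": NO_INFORMATION
      "un": UNKNOWN
      "ot": OTHER
      "white": WHITE
      "black": BLACK_AA
      "asian": ASIAN
      "hispanic": HISPANIC
  - system_id: PCORNET_ETH
    data_model: PCORNET
    entries:
      "y": HISPANIC
      "n": NOT_HISPANIC
      "r": REFUSED
      "ni": NO_INFORMATION
      "un": UNKNOWN
      "ot": OTHER
  - system_id: OMOP_RACE
    data_model: OMOP
    entries:
      "8527": WHITE
      "8516": BLACK_AA
      "8515": ASIAN
      "8557": NHPI
      "8657": AIAN
      "8522": OTHER_RACE
      "8552": UNKNOWN
      "white": WHITE
      "caucasian": WHITE
      "black": BLACK_AA
      "african american": BLACK_AA
      "asian": ASIAN
      "pacific islander": NHPI
      "hispanic": HISPANIC
      "asian indian": ASIAN_INDIAN
      "38003574": ASIAN_INDIAN
      "filipino": FILIPINO
      "chinese": CHINESE
      "korean": KOREAN
      "vietnamese": VIETNAMESE
      "japanese": JAPANESE
      "guamanian or chamorro": GUAMANIAN_CHAMORRO
      "polynesian": POLYNESIAN
      "jewish": JEWISH
  - system_id: OMOP_ETH
    data_model: OMOP
    entries:
      "38003563": HISPANIC
      "38003564": NOT_HISPANIC
      "hispanic or latino": HISPANIC
      "not hispanic or latino": NOT_HISPANIC
      "puerto rican": PUERTO_RICAN
      "mexican": MEXICAN
      "cuban": CUBAN
      "south american": SOUTH_AMERICAN
      "central american": CENTRAL_AMERICAN
      "dominican": DOMINICAN
      "spaniard": SPANIARD
  - system_id: ACT_RACE
    data_model: ACT
    entries:
      "2106-3": WHITE
      "2054-5": BLACK_AA
      "2028-9": ASIAN
      "2076-8": NHPI
      "1002-5": AIAN
      "2131-1": OTHER_RACE
      "white": WHITE
      "black": BLACK_AA
      "b": BLACK_AA
      "asian": ASIAN
      "a": ASIAN
      "declined": REFUSED
      "other": OTHER
      "hispanic": HISPANIC
  - system_id: ACT_ETH
    data_model: ACT
    entries:
      "2135-2": HISPANIC
      "2186-5": NOT_HISPANIC
      "hispanic": HISPANIC
      "ni": NO_INFORMATION
  - system_id: TRINETX_RACE
    data_model: TRINETX
    entries:
      "white": WHITE
      "2106-3": WHITE
      "black": BLACK_AA
      "black or african american": BLACK_AA
      "2054-5": BLACK_AA
      "asian": ASIAN
      "2028-9": ASIAN
      "native hawaiian or other pacific islander": NHPI
      "american indian or alaska native": AIAN
      "refused": REFUSED
      "other": OTHER
      "unknown": UNKNOWN
      "hispanic": HISPANIC
  - system_id: TRINETX_ETH
    data_model: TRINETX
    entries:
      "hispanic or latino": HISPANIC
      "not hispanic or latino": NOT_HISPANIC
      "unknown": UNKNOWN
  - system_id: LOCAL_RACE
    data_model: LOCAL
    entries:
      "white": WHITE
      "w": WHITE
      "wht": WHITE
      "caucasian": WHITE
      "european": WHITE
      "middle eastern": WHITE
      "anglo": WHITE
      "white/caucasian": WHITE
      "white non hispanic": WHITE
      "jewish": JEWISH
      "black": BLACK_AA
      "b": BLACK_AA
      "aa": BLACK_AA
      "african american": BLACK_AA
      "african-american": BLACK_AA
      "afro american": BLACK_AA
      "african": BLACK_AA
      "haitian": BLACK_AA
      "negro": BLACK_AA
      "black or african american": BLACK_AA
      "black non hispanic": BLACK_AA
      "black/african american": BLACK_AA
      "asian": ASIAN
      "a": ASIAN
      "asian american": ASIAN
      "south asian": ASIAN
      "east asian": ASIAN
      "asian indian": ASIAN_INDIAN
      "filipino": FILIPINO
      "chinese": CHINESE
      "korean": KOREAN
      "vietnamese": VIETNAMESE
      "japanese": JAPANESE
      "pacific islander": NHPI
      "native hawaiian": NHPI
      "pi": NHPI
      "guamanian or chamorro": GUAMANIAN_CHAMORRO
      "polynesian": POLYNESIAN
      "american indian": AIAN
      "native american": AIAN
      "alaska native": AIAN
      "hispanic": HISPANIC
      "latino": HISPANIC
      "hispanic or latino": HISPANIC
  - system_id: LOCAL_ETH
    data_model: LOCAL
    entries:
      "hispanic": HISPANIC
      "latino": HISPANIC
      "hispanic or latino": HISPANIC
      "non-hispanic": NOT_HISPANIC
      "not hispanic": NOT_HISPANIC
      "not hispanic or latino": NOT_HISPANIC
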