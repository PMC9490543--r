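# Canonical synonym groups used as a system-agnostic fallback when a value
# has no entry in its code system.  Groups must be pairwise disjoint.
# Values are matched after normalization (case-fold, trim, collapse spaces).
version: 1
groups:
  REFUSED: ["refused", "declined", "patient refused", "pt refused", "asked but not answered"]
  MULTIRACIAL: ["multiracial", "multi-racial", "multiple race", "two or more races", "more than one race"]
  MISSING: ["0", "null", "missing", "no information", "ni", "not available", "n/a", "no info"]
  UNKNOWN: ["unknown", "unk", "un"]
  OTHER: ["other", "other race", "ot"]
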