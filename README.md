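# raceaudit

Conformance auditing of race and ethnicity data in multi-site clinical
extracts.

## The problem

Health care institutions record patient race and ethnicity in wildly
heterogeneous ways. The federal standard (OMB 1997, carried into HL7/FHIR
with CDC codes) defines **5 minimum race categories** — American Indian or
Alaska Native (1002-5), Asian (2028-9), Black or African American (2054-5),
Native Hawaiian or Other Pacific Islander (2076-8), White (2106-3) — and a
**separate 2-category ethnicity concept** (Hispanic or Latino, 2135-2 / Not
Hispanic or Latino). Granular subcategories (Asian Indian, Guamanian or
Chamorro, Puerto Rican, ...) are meant to *roll up* into these minimums.
In practice, multi-site research enclaves receive a mixture of HL7 codes,
OMOP concept ids, PCORnet numeric codes (`05` = White, `03` = Black or
African American, ...), free-text labels, zero-filled blanks and stray
symbols, spread across OMOP, PCORnet, ACT, TriNetX and PEDSnet data-model
dialects.

`raceaudit` is for data-quality and health-equity informatics teams who
need to quantify that heterogeneity. It harmonizes source encodings
against an editable terminology registry, labels every record as
**conforming** (harmonized to a minimum category) or assigns exactly one of
seven mutually exclusive **nonconformance categories**

```
MISSING  OTHER  REFUSED  MULTIRACIAL  MISCLASSIFIED  UNINTERPRETABLE  MORE_GRANULAR
```

with the precedence `MISSING > REFUSED > OTHER > MULTIRACIAL >
MORE_GRANULAR > MISCLASSIFIED > UNINTERPRETABLE`, and aggregates weighted
reports: per-concept totals, ethnicity cross-tabs, per-data-model
conformance, and per-site reporting schemas. A seedable synthetic cohort
generator (with ground-truth mechanism labels) and a deterministic fixture
encoding the published National COVID Cohort Collaborative (N3C)
data-quality marginals are included for validation.

## Worked example

```r
library(raceaudit)

fx  <- n3c_fixture()      # 332 weighted rows standing for 6,513,464 patients
aud <- audit(fx)          # upstream mode: audit the delivered harmonization
summary(aud)
```

```
Race/ethnicity conformance audit (mode: upstream )

Total weight: 6,513,464
Race conforming:      5,167,969  (79.3%)
Ethnicity conforming: 5,456,162  (83.8%)

Nonconformance taxonomy (race):
  MISSING               734,931  (54.6% of nonconforming)
  OTHER                 356,778  (26.5% of nonconforming)
  REFUSED               107,445  (8.0% of nonconforming)
  MULTIRACIAL            98,979  (7.4% of nonconforming)
  MISCLASSIFIED          42,617  (3.2% of nonconforming)
  UNINTERPRETABLE         2,268  (0.2% of nonconforming)
  MORE_GRANULAR           2,477  (0.2% of nonconforming)

Top harmonized race concepts:
  White                       4,007,091
  No matching concept         1,169,372
  Black or African American      963,676
  Asian                         184,985
  Null                           57,523
  Unknown                        40,000
  Other                          25,000
  Other race                     19,238
  Black                          18,885
  No information                 13,000
```

79.3% of patient weight was harmonized to one of the five minimum race
categories; "No matching concept" — dropped data — is the second-largest
harmonized concept. Drilling in:

```r
fr <- attr(crosstab(aud, "race_category", "ethnicity"), "row_fractions")
pct_round(fr["OTHER", "Hispanic or Latino"])
#> [1] 61
conformance_by_model(aud)[, c("data_model", "race_fraction")]
#>     data_model race_fraction
#> 1          ACT     0.4196702
#> 2         OMOP     0.8106795
#> 3 OMOP_PEDSNET     0.6616270
#> 4      PCORNET     0.8404814
#> 5      TRINETX     0.8619080
```

61.0% of records dumped into "Other" belong to Hispanic or Latino
patients (PCORnet's specification maps Hispanic-as-race to "Other"), and
race conformance ranges from 86.2% (TriNetX) down to 66.2% (PEDSnet)
depending on the source data model.

Other entry points: `read_records()` / `run_audit()` for your own CSV
extracts, `generate_cohort(synth_config(seed = 1))` for labelled synthetic
cohorts, `apply_redaction()` for the AI/AN-into-Other obscuring policy,
and `inst/cli/raceaudit.R` for a shell interface
(`audit` / `generate` / `fixture` / `validate-terminology` subcommands).

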