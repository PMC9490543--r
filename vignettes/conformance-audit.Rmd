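---
title: "Auditing race and ethnicity conformance in multi-site clinical data"
author: "raceaudit"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The procedure and its assumptions

`raceaudit` implements a descriptive data-quality audit, not a statistical
model. Its unit of analysis is a *weighted demographic record*: one
patient (weight 1) or one aggregate stratum (weight = patient count) with
a site, a data-model dialect, raw source value(s) for race, a raw value
for ethnicity, and — optionally — the harmonized concepts an upstream
mapper delivered. The audit makes three assumptions:

1. **The OMB/HL7 minimum categories are the conformance yardstick.** A
   record's race conforms when its harmonized concept is one of the five
   minimum race categories; ethnicity conforms when it is Hispanic or
   Latino / Not Hispanic or Latino. This is a statement about standards
   adherence, not about the validity of the categories themselves.
2. **Source values are the evidence base.** Every taxonomy decision is
   driven by what the site actually transmitted, resolved through an
   explicit, editable terminology registry. There is no fuzzy matching
   and no imputation: normalization is case-fold + trim + whitespace
   collapse, nothing more, so every classification can be traced to a
   registry entry or synonym group.
3. **Weights are exchangeable.** All aggregates are weighted sums, so a
   6.5M-patient cohort and a few hundred aggregate rows with the same
   margins produce identical reports (the fixture exploits exactly this).

### Harmonization and reduction

In `recompute` mode each race value is resolved (code table first, then
the canonical synonym groups), granular concepts are rolled up to their
main parent, and the value list is reduced: no values →
`MISSING_SENTINEL`; one distinct main → that main; two or more distinct
mains → `MULTIPLE_RACE`; only flags → the first flag; nothing resolvable →
`NO_MATCHING_CONCEPT`. Two values that roll to the *same* main (e.g.
Chinese + Asian) encode one category and reduce to it, not to
multiracial. One resolvable main plus unresolvable noise keeps the main
and logs a notice; `strict = TRUE` reduces it to `NO_MATCHING_CONCEPT`
instead. In `upstream` mode (the default, and how an enclave's own
mapping is audited) the delivered `harmonized_*` columns are taken
verbatim, falling back per axis to recomputation where absent.

### The seven-way taxonomy

Nonconforming records receive exactly one category by precedence:

| order | category | trigger |
|---|---|---|
| 1 | `MISSING` | no value, or all values are missing/unknown sentinels (`0`, `Null`, `NI`, ...) |
| 2 | `REFUSED` | any refusal value (`Refused`, `Declined`, PCORnet `07`) |
| 3 | `OTHER` | any value resolving to the deprecated Other / Other race flags |
| 4 | `MULTIRACIAL` | ≥2 distinct mains in a multi-select, or a multiracial token |
| 5 | `MORE_GRANULAR` | harmonized concept is granular, never rolled up |
| 6 | `MISCLASSIFIED` | source resolves to a main (or to Hispanic/Latino in the race field) but harmonization went elsewhere |
| 7 | `UNINTERPRETABLE` | residual (`@`) |

The source tables present these as mutually exclusive without stating
tie-breaks, so the order was a genuine design choice. We resolve overlaps
toward the more specific *data-collection* phenomenon: a granular value
that was also mismapped says "this site collects granular data" before it
says "the mapping failed", hence `MORE_GRANULAR` precedes
`MISCLASSIFIED`; a refusal that was also left unmapped is still a
refusal. The order is a function argument (`precedence =`), so a
different audit philosophy is one call away. `MISCLASSIFIED`
deliberately requires *source-value evidence* — a resolvable source
string whose target differs from the harmonized concept — because without
the source value the "correct" target is unknowable.

Two pooling decisions deserve a note. `Unknown` / `No information` /
`Null` default into `MISSING`: the published missingness count ("29
distinct ways") only reconciles if these are pooled, though the top-10
concept list prints them separately; the synonym groups are editable data
if a deployment wants `Unknown` treated as its own bucket. And
nonconforming *ethnicity* is a single undifferentiated class — the source
material does not subdivide it, so neither do we.

## Tunable parameters

| parameter | default | why |
|---|---|---|
| `mode` | `upstream` | audits the mapping as delivered; `recompute` benchmarks the registry itself |
| `delimiters` | `;` `\|` `,` | multi-select separators; sites' actual delimiters are undocumented, so the set is configurable |
| `strict` | `FALSE` | conservative information retention for main+noise mixtures |
| `precedence` | see above | taxonomy tie-break order |
| `redaction_policy()` | disabled | when enabled, folds AI/AN (configurable) into `OTHER`, emulating enclave obscuring; weight is conserved and the redacted count reported |
| percent rounding | half-up, 1 decimal | matches the printed style of published audit tables; base `round()` (half-even) would not |

## The synthetic generator

`generate_cohort(synth_config(seed))` emulates the mechanisms the audit is
designed to detect: per-site data-model dialects (OMOP / PCORnet / ACT /
TriNetX / PEDSnet encodings), missingness, refusal, "Other"-dumping,
multi-select multiracial reporting, granular values left unrolled,
mismapping (correct source, wrong harmonized target), Hispanic-as-race
confusion, and uninterpretable symbols. Default mechanism rates are set
to the nonconformance landscape observed in a large COVID-era enclave
(11.3% missing, 5.5% other, 1.6% refused, 1.5% multiracial, 0.5%
mismapped, 0.2% ethnicity-in-race, and trace rates for the rest); the
race distribution defaults to a plausible large-system mix with the AI/AN
share exposed as a free parameter, since its true enclave prevalence is
unobservable by construction. Every record carries a ground-truth
mechanism label, so recovery can be checked record-for-record when
mechanisms are injected deterministically (rates 0 or 1).

What the generator does **not** emulate: correlated missingness between
race and ethnicity, site-level drift over time, free-text typos (the
registry has no fuzzy matching to exercise), within-site dialect mixing,
and realistic clinical covariates. Passing tests therefore demonstrate
that the pipeline's bookkeeping is exact under the stated mechanisms, not
that it is robust to arbitrary real-world EHR noise.

## The fixture

`n3c_fixture()` encodes the published audit marginals of the N3C Data
Enclave (6,513,464 patients, 56 sites, five data models) as ~330 weighted
aggregate rows built with integer arithmetic and no randomness. Every
printed count — the conforming concept totals, the seven nonconformance
counts, the misclassification breakdown, the ethnicity cross-cells, the
per-model strata, the 21/24/22 distinct-encoding counts with their modal
codes, the 10 reporting schemas — is reproduced by *running the audit*,
never by hard-coding report values. Quantities the publication does not
print are fixed once at plausible values and are never asserted: the
split of "No matching concept" weight across nonconforming strata (its
total, 1,169,372, is forced by the printed top-3 share), the
OMOP/PCORnet/ACT race-conformance split, the multiracial Hispanic/Latino
cell (46,916, the nearest integer consistent with the printed 47.4%), and
all site-level weights beyond the schema aggregates. The NHPI conforming
total (12,217) is the arithmetic remainder of printed totals. The second
undecipherable TriNetX token is unnamed in the source and is represented
by the placeholder `^`.

One structural choice: a site's *reporting schema* is the triple (set of
main categories reported, granular-categories flag, separate-ethnicity
flag). The granular flag is needed because the published 10-schema count
distinguishes "standard adherent" sites from "standard plus granular
extras" sites, which are identical on the other two axes.

## Numerical choices and degenerate inputs

* Percentages: `floor(x * 1000 + 0.5 + 1e-9) / 10` — half-up at one
  decimal, with an epsilon guarding binary representation of exact
  halves.
* Empty margins report `NA` ("undefined"), never 0; an empty input yields
  a zero-total report, not a division error.
* Unknown upstream concepts are mapped to `NO_MATCHING_CONCEPT` with a
  logged count; unknown source strings return `NO_MATCH` rather than
  erroring, so a single bad row cannot abort an audit.
* Ties in greedy fixture allocation and round-robins are broken by fixed
  build order; the whole pipeline is deterministic, and report JSON is
  byte-identical across runs on identical input.

## Problem sizes used by the test suite

The suite audits the fixture (~330 rows standing for 6.5M patients),
50 random 200-record cohorts for the partition invariant, 100–500-record
cohorts for the deterministic-injection recovery checks, and one
100,000-record cohort for the stochastic rate-recovery check against 99%
binomial intervals (`qbinom(c(0.005, 0.995), n, p)`). These sizes give
exact or near-exact checks in seconds; the pipeline itself is vectorized
and scales linearly in records.

## Known limitations

* The shipped registry covers the codes and labels documented for the
  audited enclave plus common variants — a few hundred entries, not the
  ~900-concept CDC granular hierarchy. It is deliberately file-based and
  user-extensible.
* `upstream` mode audits whatever harmonization it is given; it cannot
  detect a mismap whose source value is itself uninterpretable.
* The distribution comparison takes user-supplied reference tables only
  (no census downloads) and performs no statistical testing — the audit
  is descriptive by design.
* Site anonymity in real enclaves means provenance below the site id is
  out of reach; the audit cannot say *why* a site's feed is nonconforming.
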