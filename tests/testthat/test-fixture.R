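# The fixture is audited with the standard pipeline; every assertion below
# is a count the source enclave publication prints (or a derived remainder),
# recomputed here rather than read from the fixture's construction tables.

fx_aud <- audit(n3c_fixture())

test_that("fixture reproduces the published conforming race counts", {
  r <- fx_aud$report
  expect_equal(r$total_weight, 6513464)
  expect_equal(r$race_conforming_weight, 5167969)
  expect_equal(r$concept_weights$WHITE, 4007091)
  expect_equal(r$concept_weights$BLACK_AA, 963676)
  expect_equal(r$concept_weights$ASIAN, 184985)
  expect_equal(r$concept_weights$NHPI, 12217)   # remainder of the printed totals
  expect_null(r$concept_weights$AIAN)           # obscured upstream
  # "No matching concept" is the second-largest harmonized concept
  cw <- unlist(r$concept_weights)
  expect_equal(names(sort(cw, decreasing = TRUE))[2], "NO_MATCHING_CONCEPT")
  expect_equal(unname(cw["NO_MATCHING_CONCEPT"]), 1169372)
})

test_that("fixture reproduces the seven published nonconformance counts", {
  cw <- fx_aud$report$race_category_weights
  expect_equal(cw$MISSING, 734931)
  expect_equal(cw$OTHER, 356778)
  expect_equal(cw$REFUSED, 107445)
  expect_equal(cw$MULTIRACIAL, 98979)
  expect_equal(cw$MISCLASSIFIED, 42617)
  expect_equal(cw$UNINTERPRETABLE, 2268)
  expect_equal(cw$MORE_GRANULAR, 2477)
})

test_that("fixture reproduces the misclassification breakdown by source concept", {
  rec <- fx_aud$records
  mis <- rec[rec$race_category == "MISCLASSIFIED", ]
  by_src <- wt_sum(mis$weight, ifelse(is.na(mis$source_main),
                                      "ETHNICITY_IN_RACE", mis$source_main))
  expect_equal(unname(by_src["BLACK_AA"]), 19415)
  expect_equal(unname(by_src["ETHNICITY_IN_RACE"]), 11728)
  expect_equal(unname(by_src["WHITE"]), 6557)
  expect_equal(unname(by_src["NHPI"]), 3067)
  expect_equal(unname(by_src["ASIAN"]), 1850)
  # of the Hispanic-in-race stratum, 2,258 are Not Hispanic or Latino in the
  # ethnicity field
  eir <- rec[rec$misclass_subtype == "ETHNICITY_IN_RACE", ]
  expect_equal(sum(eir$weight[eir$ethnicity_main == "NOT_HISPANIC"]), 2258)
})

test_that("fixture reproduces the ethnicity margins and cross-cells", {
  r <- fx_aud$report
  rec <- fx_aud$records
  expect_equal(r$ethnicity_conforming_weight, 5456162)
  hl <- rec$ethnicity_main == "HISPANIC"
  expect_equal(sum(rec$weight[hl]), 773695)
  expect_equal(sum(rec$weight[hl & rec$race_status == "NONCONFORMING"]), 399831)
  ct <- crosstab(fx_aud, "race_category", "ethnicity")
  expect_equal(unname(ct["MISSING", "Hispanic or Latino"]), 99853)
  expect_equal(unname(ct["OTHER", "Hispanic or Latino"]), 217476)
  expect_equal(unname(ct["REFUSED", "Hispanic or Latino"]), 22683)
})

test_that("fixture reproduces the per-data-model strata", {
  pm <- fx_aud$report$per_model
  g <- function(m, col) pm[pm$data_model == m, col]
  expect_equal(g("TRINETX", "total_weight"), 825001)
  expect_equal(g("TRINETX", "race_conforming"), 711075)
  expect_equal(g("OMOP_PEDSNET", "total_weight"), 97097)
  expect_equal(g("OMOP_PEDSNET", "race_conforming"), 64242)
  expect_equal(g("PCORNET", "total_weight"), 2305731)
  expect_equal(g("PCORNET", "ethnicity_conforming"), 2146229)
  expect_equal(g("ACT", "total_weight"), 534179)
  expect_equal(g("ACT", "ethnicity_conforming"), 271304)
})

test_that("fixture realizes 56 sites in 10 reporting schemas", {
  ss <- detect_site_schemas(fx_aud)
  expect_equal(nrow(ss), 56L)
  expect_equal(attr(ss, "n_schemas"), 10L)
  # published aggregates: 41 standard-adherent, 5 granular-extended,
  # 10 omitting a category, 51 with an ethnicity field
  all4 <- vapply(strsplit(ss$categories, ","), length, integer(1)) == 4L
  expect_equal(sum(all4 & !ss$has_granular), 41L)
  expect_equal(sum(all4 & ss$has_granular), 5L)
  expect_equal(sum(!all4), 10L)
  expect_equal(sum(ss$has_ethnicity_field), 51L)
  # White is the only category reported by every site
  expect_true(all(grepl("WHITE", ss$categories)))
})

test_that("fixture multiracial and missing details match the published counts", {
  rec <- fx_aud$records
  mr <- rec[rec$race_category == "MULTIRACIAL", ]
  true_multi <- mr$n_distinct_mains >= 2L
  expect_equal(sum(mr$weight[true_multi]), 3764)
  wb <- normalize_value(mr$race_value) == "white;black or african american"
  expect_equal(sum(mr$weight[wb]), 1563)
  zero <- rec[normalize_value(rec$race_value) == "0", ]
  expect_equal(sum(zero$weight), 348057)
  expect_true(all(zero$race_category == "MISSING"))
})
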