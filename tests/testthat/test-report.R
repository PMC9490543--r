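test_that("percent rounding is half-up to one decimal", {
  expect_equal(pct_round(0.1005), 10.1)   # base round() would give 10.0
  expect_equal(pct_round(217476 / 356778), 61.0)
  expect_equal(pct_round(0.999999), 100.0)
  expect_true(is.na(pct_round(NA_real_)))
})

test_that("summarize handles the trivial and empty margins", {
  one <- audit(rec("White", harmonized_race = "WHITE"), REG)
  expect_equal(one$report$race_conforming_pct, 100.0)

  empty <- audit(rec("White")[0, ], REG)
  expect_equal(empty$report$total_weight, 0)
  expect_true(is.na(empty$report$race_conforming_pct))
})

test_that("cross-tab cells sum to their margins and bad dimensions error", {
  aud <- audit(generate_cohort(synth_config(seed = 5, n_patients = 500))$records, REG)
  ct <- crosstab(aud, "race_category", "data_model")
  cats <- wt_sum(aud$records$weight,
                 ifelse(aud$records$race_status == "CONFORMING", "CONFORMING",
                        aud$records$race_category))
  expect_equal(rowSums(ct)[names(cats)], cats)
  expect_equal(sum(ct), aud$report$total_weight)
  expect_error(crosstab(aud, "race_category", "planet"), "unknown crosstab dimension")
})

test_that("site schema detection distinguishes category sets and ethnicity fields", {
  df <- recs(rec("White", harmonized_race = "WHITE", site_id = "X",
                 ethnicity_value = "Hispanic"),
             rec("Black", harmonized_race = "BLACK_AA", site_id = "X",
                 ethnicity_value = "Hispanic"),
             rec("White", harmonized_race = "WHITE", site_id = "Y",
                 ethnicity_value = "Hispanic"),
             rec("Black", harmonized_race = "BLACK_AA", site_id = "Y",
                 ethnicity_value = "Hispanic"),
             rec("White", harmonized_race = "WHITE", site_id = "Z",
                 ethnicity_system = "", ethnicity_value = ""))
  ss <- detect_site_schemas(audit(df, REG))
  expect_equal(nrow(ss), 3L)
  expect_equal(attr(ss, "n_schemas"), 2L)  # X and Y share one schema
  expect_false(ss$has_ethnicity_field[ss$site_id == "Z"])
})

test_that("per-model conformance omits absent models", {
  aud <- audit(rec("05", race_system = "PCORNET_RACE", data_model = "PCORNET",
                   harmonized_race = "WHITE"), REG)
  pm <- conformance_by_model(aud)
  expect_equal(pm$data_model, "PCORNET")
  expect_equal(pm$race_fraction, 1)
})

test_that("distribution comparison aligns categories and flags gaps", {
  aud <- audit(n3c_fixture())
  self <- stats::setNames(compare_distributions(aud, list())$audit_fraction,
                          compare_distributions(aud, list())$category)
  cmp <- compare_distributions(aud, list(self = self))
  expect_equal(cmp$diff_self, rep(0, nrow(cmp)))
  # a reference lacking AI/AN marks that row not applicable
  ref <- self[names(self) != "American Indian or Alaska Native"]
  cmp2 <- compare_distributions(aud, list(acs = ref))
  expect_true(is.na(cmp2$acs[cmp2$category == "American Indian or Alaska Native"]))
  expect_error(compare_distributions(aud, list(bad = c(White = 1.2))),
               "fractions")
})

test_that("summaries are permutation-invariant and weight-linear", {
  cohort <- generate_cohort(synth_config(seed = 9, n_patients = 400))
  aud <- audit(cohort$records, REG)
  shuffled <- cohort$records[sample(nrow(cohort$records)), ]
  expect_equal(audit(shuffled, REG)$report$race_conforming_pct,
               aud$report$race_conforming_pct)
  scaled <- cohort$records
  scaled$weight <- scaled$weight * 3
  aud3 <- audit(scaled, REG)
  expect_equal(aud3$report$race_conforming_pct, aud$report$race_conforming_pct)
  expect_equal(aud3$report$total_weight, 3 * aud$report$total_weight)
})
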