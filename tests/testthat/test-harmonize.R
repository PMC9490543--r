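test_that("recompute reduction follows the roll-up and multi-select rules", {
  r <- harmonize_records(REG, recs(
    rec("05", race_system = "PCORNET_RACE", data_model = "PCORNET"),
    rec(""),
    rec("Asian Indian", race_system = "OMOP_RACE"),
    rec("White;Black"),
    rec("Chinese;Asian", race_system = "OMOP_RACE")), mode = "recompute")
  expect_equal(r$race_main[1], "WHITE")
  expect_equal(r$race_main[2], "MISSING_SENTINEL")
  expect_equal(r$race_concepts[3], "ASIAN_INDIAN")
  expect_equal(r$race_main[3], "ASIAN")
  expect_equal(r$race_main[4], "MULTIPLE_RACE")
  # two values rolling to the same main reduce to that main, not multiracial
  expect_equal(r$race_main[5], "ASIAN")
})

test_that("two-token reductions match brute-force enumeration over main labels", {
  labels <- c(WHITE = "White", BLACK_AA = "Black", ASIAN = "Asian",
              NHPI = "Pacific Islander", AIAN = "American Indian")
  cases <- expand.grid(a = names(labels), b = names(labels),
                       stringsAsFactors = FALSE)
  input <- do.call(rbind, lapply(seq_len(nrow(cases)), function(i)
    rec(paste(labels[cases$a[i]], labels[cases$b[i]], sep = ";"))))
  got <- harmonize_records(REG, input, mode = "recompute")$race_main
  expected <- ifelse(cases$a == cases$b, cases$a, "MULTIPLE_RACE")
  expect_equal(got, expected)
})

test_that("a resolvable main plus noise keeps the main unless strict", {
  r <- harmonize_records(REG, rec("White;zzz"), mode = "recompute")
  expect_equal(r$race_main, "WHITE")
  expect_equal(attr(r, "harmonize_log")$n_noise_reduced, 1L)
  r2 <- harmonize_records(REG, rec("White;zzz"), mode = "recompute", strict = TRUE)
  expect_equal(r2$race_main, "NO_MATCHING_CONCEPT")
})

test_that("ethnicity reduction rolls granular subcategories up to Hispanic or Latino", {
  r <- harmonize_records(REG, recs(
    rec(ethnicity_value = "Puerto Rican", ethnicity_system = "OMOP_ETH"),
    rec(ethnicity_value = "Y", ethnicity_system = "PCORNET_ETH", data_model = "PCORNET"),
    rec(ethnicity_value = ""),
    rec(ethnicity_value = "???")), mode = "recompute")
  expect_equal(r$ethnicity_main,
               c("HISPANIC", "HISPANIC", "MISSING_SENTINEL", "NO_MATCHING_CONCEPT"))
})

test_that("upstream mode takes the delivered harmonization verbatim, with fallback", {
  r <- harmonize_records(REG, recs(
    rec("Asian Indian", race_system = "OMOP_RACE", harmonized_race = "ASIAN_INDIAN"),
    rec("05", race_system = "PCORNET_RACE", data_model = "PCORNET")), mode = "upstream")
  expect_equal(r$race_main, c("ASIAN_INDIAN", "WHITE"))
  expect_equal(r$provenance_race, c("UPSTREAM", "RECOMPUTED"))
})

test_that("recompute harmonization is a pure function of registry and records", {
  cohort <- generate_cohort(synth_config(seed = 7, n_patients = 300))
  a <- harmonize_records(REG, cohort$records, mode = "recompute")
  b <- harmonize_records(REG, cohort$records, mode = "recompute")
  expect_identical(a, b)
})

test_that("with zero injected error, upstream and recomputed harmonization agree", {
  cfg <- synth_config(seed = 11, n_patients = 500,
                      rates = list(p_missing = 0, p_refused = 0, p_other = 0,
                                   p_multiracial = 0, p_granular_unrolled = 0,
                                   p_mismap = 0, p_ethnicity_in_race = 0,
                                   p_uninterpretable = 0))
  cohort <- generate_cohort(cfg)
  h <- harmonize_records(REG, cohort$records, mode = "both")
  expect_equal(h$race_main, h$race_main_recomputed)
})

test_that("the source-encoding tabulation counts weights and distinct variants", {
  one <- tabulate_source_encodings(REG, rec("05", race_system = "PCORNET_RACE",
                                            data_model = "PCORNET", weight = 7))
  expect_equal(nrow(one), 1L)
  expect_equal(one$weight, 7)
  expect_equal(one$mapped_concept, "WHITE")

  tab <- tabulate_source_encodings(REG, n3c_fixture(), "race")
  n_enc <- table(tab$mapped_concept)
  expect_equal(unname(n_enc["WHITE"]), 21L)
  expect_equal(unname(n_enc["BLACK_AA"]), 24L)
  expect_equal(unname(n_enc["ASIAN"]), 22L)
  # modal codes carry the published weights
  expect_equal(tab$weight[tab$system_id == "PCORNET_RACE" & tab$value == "05"], 1442961)
  expect_equal(tab$weight[tab$system_id == "PCORNET_RACE" & tab$value == "03"], 411537)
  expect_equal(tab$weight[tab$system_id == "PCORNET_RACE" & tab$value == "02"], 77426)
})
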