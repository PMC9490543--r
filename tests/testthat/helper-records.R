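# shared fixtures: registry loaded once, small record builders

REG <- load_registry()

# one-row record builder with sensible defaults
rec <- function(race_value = "", race_system = "LOCAL_RACE",
                harmonized_race = "", ethnicity_value = "",
                ethnicity_system = "LOCAL_ETH", harmonized_ethnicity = "",
                site_id = "S1", data_model = "OMOP", weight = 1,
                patient_id = "P1") {
  data.frame(patient_id = patient_id, site_id = site_id,
             data_model = data_model, race_system = race_system,
             race_value = race_value, ethnicity_system = ethnicity_system,
             ethnicity_value = ethnicity_value,
             harmonized_race = harmonized_race,
             harmonized_ethnicity = harmonized_ethnicity,
             weight = weight, stringsAsFactors = FALSE)
}

recs <- function(...) do.call(rbind, list(...))

write_temp_csv <- function(df) {
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE)
  p
}
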