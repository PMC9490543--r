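# Synthetic multi-site cohort generator with labelled error mechanisms.

MECHANISMS <- c("missing", "refused", "other", "multiracial",
                "granular_unrolled", "mismap", "ethnicity_in_race",
                "uninterpretable")
MECHANISM_CATEGORY <- c(missing = "MISSING", refused = "REFUSED",
                        other = "OTHER", multiracial = "MULTIRACIAL",
                        granular_unrolled = "MORE_GRANULAR",
                        mismap = "MISCLASSIFIED",
                        ethnicity_in_race = "MISCLASSIFIED",
                        uninterpretable = "UNINTERPRETABLE", none = "NONE")

# per-model source dialects used by the generator
MODEL_RACE_SYSTEM <- c(OMOP = "OMOP_RACE", OMOP_PEDSNET = "OMOP_RACE",
                       PCORNET = "PCORNET_RACE", ACT = "ACT_RACE",
                       TRINETX = "TRINETX_RACE", LOCAL = "LOCAL_RACE")
MODEL_ETH_SYSTEM <- c(OMOP = "OMOP_ETH", OMOP_PEDSNET = "OMOP_ETH",
                      PCORNET = "PCORNET_ETH", ACT = "ACT_ETH",
                      TRINETX = "TRINETX_ETH", LOCAL = "LOCAL_ETH")
MODEL_RACE_CODE <- list(
  OMOP = c(WHITE = "8527", BLACK_AA = "8516", ASIAN = "8515", NHPI = "8557", AIAN = "8657"),
  OMOP_PEDSNET = c(WHITE = "8527", BLACK_AA = "8516", ASIAN = "8515", NHPI = "8557", AIAN = "8657"),
  PCORNET = c(WHITE = "05", BLACK_AA = "03", ASIAN = "02", NHPI = "04", AIAN = "01"),
  ACT = c(WHITE = "2106-3", BLACK_AA = "2054-5", ASIAN = "2028-9", NHPI = "2076-8", AIAN = "1002-5"),
  TRINETX = c(WHITE = "White", BLACK_AA = "Black or African American", ASIAN = "Asian",
              NHPI = "Native Hawaiian or Other Pacific Islander",
              AIAN = "American Indian or Alaska Native"),
  LOCAL = c(WHITE = "White", BLACK_AA = "Black", ASIAN = "Asian",
            NHPI = "Pacific Islander", AIAN = "American Indian"))
MODEL_ETH_CODE <- list(
  OMOP = c(HISPANIC = "38003563", NOT_HISPANIC = "38003564"),
  OMOP_PEDSNET = c(HISPANIC = "38003563", NOT_HISPANIC = "38003564"),
  PCORNET = c(HISPANIC = "Y", NOT_HISPANIC = "N"),
  ACT = c(HISPANIC = "2135-2", NOT_HISPANIC = "2186-5"),
  TRINETX = c(HISPANIC = "Hispanic or Latino", NOT_HISPANIC = "Not Hispanic or Latino"),
  LOCAL = c(HISPANIC = "Hispanic", NOT_HISPANIC = "Not Hispanic"))
GRANULAR_RACE <- c(ASIAN_INDIAN = "Asian Indian", FILIPINO = "Filipino",
                   CHINESE = "Chinese", KOREAN = "Korean",
                   VIETNAMESE = "Vietnamese", JAPANESE = "Japanese",
                   GUAMANIAN_CHAMORRO = "Guamanian or Chamorro",
                   POLYNESIAN = "Polynesian", JEWISH = "Jewish")

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the error landscape of a large multi-site COVID-era
#' enclave: mechanism rates close to the observed nonconformance shares
#' (11.3\% missing, 5.5\% "Other", 1.6\% refused, 1.5\% multiracial, 0.65\%
#' mismapped, and trace rates of unrolled-granular and uninterpretable
#' codes), a five-model site mix, and a separate ethnicity field at most
#' sites.  The AI/AN share is a free parameter (its true enclave prevalence
#' is unobservable because those records are obscured).
#'
#' @param seed integer seed (mandatory; the generator is deterministic given
#'   the seed).
#' @param n_patients number of patient-level records.
#' @param n_sites number of sites; data models are assigned cyclically from
#'   \code{models}.
#' @param models data-model pool for sites.
#' @param rates named list of mechanism probabilities in \[0, 1\] summing to
#'   at most 1 (names: \code{p_missing}, \code{p_refused}, \code{p_other},
#'   \code{p_multiracial}, \code{p_granular_unrolled}, \code{p_mismap},
#'   \code{p_ethnicity_in_race}, \code{p_uninterpretable}).
#' @param race_dist named distribution over the 5 main race concepts
#'   (sums to 1).
#' @param eth_dist named distribution over the 2 ethnicity concepts.
#' @param p_ethnicity_missing probability that ethnicity is unrecorded.
#' @param site_eth_field logical vector (recycled over sites): does the site
#'   have a separate ethnicity field?
#' @return a \code{synth_config} list.
#' @export
synth_config <- function(seed,
                         n_patients = 2000,
                         n_sites = 8,
                         models = c("OMOP", "PCORNET", "ACT", "TRINETX", "OMOP_PEDSNET"),
                         rates = list(),
                         race_dist = c(WHITE = 0.63, BLACK_AA = 0.22, ASIAN = 0.10,
                                       NHPI = 0.04, AIAN = 0.01),
                         eth_dist = c(HISPANIC = 0.19, NOT_HISPANIC = 0.81),
                         p_ethnicity_missing = 0.16,
                         site_eth_field = TRUE) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    abort_config("a single integer seed is mandatory")
  default_rates <- list(p_missing = 0.113, p_refused = 0.016, p_other = 0.055,
                        p_multiracial = 0.015, p_granular_unrolled = 0.0004,
                        p_mismap = 0.005, p_ethnicity_in_race = 0.002,
                        p_uninterpretable = 0.0003)
  bad <- setdiff(names(rates), names(default_rates))
  if (length(bad)) abort_config("unknown rate(s): %s", paste(bad, collapse = ", "))
  rates <- utils::modifyList(default_rates, rates)
  rv <- unlist(rates)
  if (any(rv < 0 | rv > 1) || sum(rv) > 1)
    abort_config("mechanism rates must lie in [0,1] and sum to at most 1")
  if (!setequal(names(race_dist), RACE_MAINS) || abs(sum(race_dist) - 1) > 1e-8)
    abort_config("race_dist must be a distribution over the 5 main race concepts")
  if (!setequal(names(eth_dist), ETH_MAINS) || abs(sum(eth_dist) - 1) > 1e-8)
    abort_config("eth_dist must be a distribution over the 2 ethnicity concepts")
  if (p_ethnicity_missing < 0 || p_ethnicity_missing > 1)
    abort_config("p_ethnicity_missing must lie in [0,1]")
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 n_sites = as.integer(n_sites), models = models, rates = rates,
                 race_dist = race_dist, eth_dist = eth_dist,
                 p_ethnicity_missing = p_ethnicity_missing,
                 site_eth_field = rep_len(site_eth_field, n_sites)),
            class = "synth_config")
}

#' Generate a synthetic multi-site cohort with ground truth
#'
#' Draws each patient's true race and ethnicity from the configured
#' distributions, assigns a site (hence a data-model dialect), optionally
#' injects one labelled error mechanism per record, and emits both the
#' source encoding a site would report and the harmonized concept an
#' upstream mapper would deliver (including the deliberate errors for the
#' mismapping and unrolled-granular mechanisms).  Deterministic given the
#' seed.
#'
#' @param config a \code{\link{synth_config}}.
#' @return list with \code{records} (a record data.frame, weight 1 per row)
#'   and \code{truth} (patient id, true race and ethnicity, injected
#'   mechanism label: one of the seven taxonomy categories or \code{NONE}).
#' @export
#' @examples
#' cohort <- generate_cohort(synth_config(seed = 1, n_patients = 200))
#' table(cohort$truth$mechanism)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed, kind = "Mersenne-Twister")
  n <- config$n_patients
  site_model <- rep_len(config$models, config$n_sites)
  site_ids <- sprintf("SYN-%02d", seq_len(config$n_sites))

  site_i <- sample.int(config$n_sites, n, replace = TRUE)
  true_race <- sample(names(config$race_dist), n, TRUE, prob = config$race_dist)
  true_eth <- sample(names(config$eth_dist), n, TRUE, prob = config$eth_dist)
  rv <- unlist(config$rates)
  mech <- sample(c(MECHANISMS, "none"), n, TRUE, prob = c(rv, 1 - sum(rv)))

  model <- site_model[site_i]
  race_system <- unname(MODEL_RACE_SYSTEM[model])
  eth_system <- unname(MODEL_ETH_SYSTEM[model])
  code_of <- function(mod, race) {
    vapply(seq_along(mod), function(i) MODEL_RACE_CODE[[mod[i]]][[race[i]]], character(1))
  }

  race_value <- code_of(model, true_race)
  harmonized_race <- true_race

  i <- mech == "missing"
  race_value[i] <- ""; harmonized_race[i] <- "NO_MATCHING_CONCEPT"
  i <- mech == "refused"
  race_value[i] <- "Refused"; harmonized_race[i] <- "NO_MATCHING_CONCEPT"
  i <- mech == "other"
  race_value[i] <- "Other"; harmonized_race[i] <- "OTHER"
  i <- mech == "uninterpretable"
  race_value[i] <- "@"; harmonized_race[i] <- "NO_MATCHING_CONCEPT"
  i <- mech == "ethnicity_in_race"
  race_value[i] <- "Hispanic"; harmonized_race[i] <- "NO_MATCHING_CONCEPT"
  i <- mech == "mismap"  # correct source encoding, wrong harmonized target
  harmonized_race[i] <- "NO_MATCHING_CONCEPT"
  i <- which(mech == "multiracial")
  if (length(i)) {
    second <- vapply(true_race[i], function(r) {
      pool <- setdiff(RACE_MAINS, r)
      pool[1L + (match(r, RACE_MAINS) %% length(pool))]
    }, character(1))
    race_value[i] <- paste(code_of(model[i], true_race[i]),
                           code_of(model[i], second), sep = ";")
    harmonized_race[i] <- "NO_MATCHING_CONCEPT"
  }
  i <- which(mech == "granular_unrolled")
  if (length(i)) {
    g <- sample(names(GRANULAR_RACE), length(i), replace = TRUE)
    # ground truth follows the granular concept's main parent
    parent_of <- c(ASIAN_INDIAN = "ASIAN", FILIPINO = "ASIAN", CHINESE = "ASIAN",
                   KOREAN = "ASIAN", VIETNAMESE = "ASIAN", JAPANESE = "ASIAN",
                   GUAMANIAN_CHAMORRO = "NHPI", POLYNESIAN = "NHPI", JEWISH = "WHITE")
    true_race[i] <- unname(parent_of[g])
    race_value[i] <- unname(GRANULAR_RACE[g])
    harmonized_race[i] <- g
  }

  eth_missing <- stats::runif(n) < config$p_ethnicity_missing
  no_field <- !config$site_eth_field[site_i]
  eth_value <- vapply(seq_len(n), function(k) MODEL_ETH_CODE[[model[k]]][[true_eth[k]]],
                      character(1))
  harmonized_eth <- true_eth
  eth_value[eth_missing] <- ""
  harmonized_eth[eth_missing] <- "NO_MATCHING_CONCEPT"
  eth_value[no_field] <- ""; eth_system[no_field] <- ""; harmonized_eth[no_field] <- ""

  records <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    site_id = site_ids[site_i],
    data_model = model,
    race_system = race_system,
    race_value = race_value,
    ethnicity_system = eth_system,
    ethnicity_value = eth_value,
    harmonized_race = harmonized_race,
    harmonized_ethnicity = harmonized_eth,
    weight = rep(1, n),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    patient_id = records$patient_id,
    true_race = true_race,
    true_ethnicity = true_eth,
    mechanism = unname(MECHANISM_CATEGORY[mech]),
    stringsAsFactors = FALSE)
  list(records = validate_records(records), truth = truth, config = config)
}
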