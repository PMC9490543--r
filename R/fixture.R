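# Deterministic weighted fixture encoding the published race/ethnicity
# data-quality marginals of the N3C Data Enclave (6,513,464 patients from
# 56 sites across five common-data-model dialects).  The fixture is a few
# hundred weighted aggregate rows, not patient-level data; auditing it with
# the standard pipeline reproduces the published counts exactly.  Weights
# the source tables do not pin down (e.g. how "No matching concept" splits
# across nonconforming strata) are fixed here at plausible values and are
# not asserted anywhere.

fixture_base_rows <- function() {
  f <- function(id, category, model, system, value, hrace, weight, granular = FALSE)
    data.frame(id = id, category = category, model = model, system = system,
               value = value, hrace = hrace, weight = weight, granular = granular,
               stringsAsFactors = FALSE)
  rows <- list(
    # ---- conforming White (21 distinct source encodings across the cohort) ----
    f("w1", "CONF", "PCORNET", "PCORNET_RACE", "05", "WHITE", 1442961),
    f("w2", "CONF", "PCORNET", "PCORNET_RACE", "White", "WHITE", 2000),
    f("w3", "CONF", "TRINETX", "TRINETX_RACE", "White", "WHITE", 550000),
    f("w4", "CONF", "TRINETX", "TRINETX_RACE", "2106-3", "WHITE", 50000),
    f("w5", "CONF", "OMOP", "OMOP_RACE", "8527", "WHITE", 1200000),
    f("w5p", "CONF", "OMOP_PEDSNET", "OMOP_RACE", "8527", "WHITE", 50000),
    f("w6", "CONF", "OMOP", "OMOP_RACE", "White", "WHITE", 300000),
    f("w7", "CONF", "ACT", "ACT_RACE", "2106-3", "WHITE", 140000),
    f("w8", "CONF", "ACT", "ACT_RACE", "White", "WHITE", 10000),
    f("w9", "CONF", "OMOP", "CDC_RACE", "2106-3", "WHITE", 150000),
    f("w10", "CONF", "OMOP", "CDC_RACE", "White", "WHITE", 20000),
    f("w11", "CONF", "OMOP", "LOCAL_RACE", "White", "WHITE", 50000),
    f("w12", "CONF", "OMOP", "LOCAL_RACE", "W", "WHITE", 10000),
    f("w13", "CONF", "OMOP", "LOCAL_RACE", "Caucasian", "WHITE", 15000),
    f("w14", "CONF", "OMOP", "LOCAL_RACE", "European", "WHITE", 5000),
    f("w15", "CONF", "OMOP", "LOCAL_RACE", "Middle Eastern", "WHITE", 2000),
    f("w16", "CONF", "OMOP", "LOCAL_RACE", "Anglo", "WHITE", 1000),
    f("w17", "CONF", "OMOP", "LOCAL_RACE", "WHT", "WHITE", 500),
    f("w18", "CONF", "OMOP", "LOCAL_RACE", "White/Caucasian", "WHITE", 3000),
    f("w19", "CONF", "OMOP", "LOCAL_RACE", "Jewish", "WHITE", 141, granular = TRUE),
    f("w20", "CONF", "OMOP", "OMOP_RACE", "Caucasian", "WHITE", 4000),
    f("w21", "CONF", "OMOP", "LOCAL_RACE", "White Non Hispanic", "WHITE", 1489),
    # ---- conforming Black or African American (24 encodings) ----
    f("b1", "CONF", "PCORNET", "PCORNET_RACE", "03", "BLACK_AA", 411537),
    f("b2", "CONF", "TRINETX", "TRINETX_RACE", "Black or African American", "BLACK_AA", 65000),
    f("b3", "CONF", "OMOP", "OMOP_RACE", "8516", "BLACK_AA", 250000),
    f("b3p", "CONF", "OMOP_PEDSNET", "OMOP_RACE", "8516", "BLACK_AA", 10000),
    f("b4", "CONF", "OMOP", "OMOP_RACE", "Black", "BLACK_AA", 30000),
    f("b5", "CONF", "ACT", "ACT_RACE", "2054-5", "BLACK_AA", 45000),
    f("b6", "CONF", "OMOP", "CDC_RACE", "2054-5", "BLACK_AA", 40000),
    f("b7", "CONF", "OMOP", "LOCAL_RACE", "Black", "BLACK_AA", 25000),
    f("b8", "CONF", "OMOP", "LOCAL_RACE", "African American", "BLACK_AA", 20000),
    f("b9", "CONF", "OMOP", "LOCAL_RACE", "B", "BLACK_AA", 5000),
    f("b10", "CONF", "OMOP", "LOCAL_RACE", "Black/African American", "BLACK_AA", 8000),
    f("b11", "CONF", "OMOP", "LOCAL_RACE", "AA", "BLACK_AA", 2000),
    f("b12", "CONF", "OMOP", "LOCAL_RACE", "Haitian", "BLACK_AA", 1000),
    f("b13", "CONF", "OMOP", "LOCAL_RACE", "African", "BLACK_AA", 1500),
    f("b14", "CONF", "OMOP", "LOCAL_RACE", "Afro American", "BLACK_AA", 500),
    f("b15", "CONF", "OMOP", "CDC_RACE", "Black", "BLACK_AA", 3000),
    f("b16", "CONF", "ACT", "ACT_RACE", "Black", "BLACK_AA", 4000),
    f("b17", "CONF", "TRINETX", "TRINETX_RACE", "2054-5", "BLACK_AA", 10000),
    f("b18", "CONF", "OMOP", "LOCAL_RACE", "Black or African American", "BLACK_AA", 10000),
    f("b19", "CONF", "OMOP", "LOCAL_RACE", "Black Non Hispanic", "BLACK_AA", 6039),
    f("b20", "CONF", "OMOP", "LOCAL_RACE", "African-American", "BLACK_AA", 4000),
    f("b21", "CONF", "OMOP", "OMOP_RACE", "African American", "BLACK_AA", 6000),
    f("b22", "CONF", "ACT", "ACT_RACE", "B", "BLACK_AA", 1000),
    f("b23", "CONF", "OMOP", "LOCAL_RACE", "Negro", "BLACK_AA", 100),
    f("b24", "CONF", "TRINETX", "TRINETX_RACE", "Black", "BLACK_AA", 5000),
    # ---- conforming Asian (22 encodings incl. rolled-up granular) ----
    f("a1", "CONF", "PCORNET", "PCORNET_RACE", "02", "ASIAN", 77426),
    f("a2", "CONF", "TRINETX", "TRINETX_RACE", "Asian", "ASIAN", 25000),
    f("a3", "CONF", "OMOP", "OMOP_RACE", "8515", "ASIAN", 30000),
    f("a3p", "CONF", "OMOP_PEDSNET", "OMOP_RACE", "8515", "ASIAN", 4000),
    f("a4", "CONF", "OMOP", "OMOP_RACE", "Asian", "ASIAN", 8000),
    f("a5", "CONF", "ACT", "ACT_RACE", "2028-9", "ASIAN", 19500),
    f("a6", "CONF", "ACT", "ACT_RACE", "Asian", "ASIAN", 3000),
    f("a7", "CONF", "OMOP", "CDC_RACE", "2028-9", "ASIAN", 5000),
    f("a8", "CONF", "OMOP", "LOCAL_RACE", "Asian", "ASIAN", 4000),
    f("a9", "CONF", "OMOP", "LOCAL_RACE", "A", "ASIAN", 1655),
    f("a10", "CONF", "OMOP", "LOCAL_RACE", "Asian American", "ASIAN", 800),
    f("a11", "CONF", "OMOP", "OMOP_RACE", "Asian Indian", "ASIAN", 388, granular = TRUE),
    f("a12", "CONF", "OMOP", "OMOP_RACE", "Filipino", "ASIAN", 40, granular = TRUE),
    f("a13", "CONF", "OMOP", "OMOP_RACE", "Chinese", "ASIAN", 50, granular = TRUE),
    f("a14", "CONF", "OMOP", "OMOP_RACE", "Korean", "ASIAN", 30, granular = TRUE),
    f("a15", "CONF", "OMOP", "OMOP_RACE", "Vietnamese", "ASIAN", 25, granular = TRUE),
    f("a16", "CONF", "OMOP", "OMOP_RACE", "Japanese", "ASIAN", 13, granular = TRUE),
    f("a17", "CONF", "OMOP", "CDC_RACE", "Asian", "ASIAN", 1000),
    f("a18", "CONF", "OMOP", "LOCAL_RACE", "South Asian", "ASIAN", 500),
    f("a19", "CONF", "TRINETX", "TRINETX_RACE", "2028-9", "ASIAN", 3858),
    f("a20", "CONF", "OMOP", "LOCAL_RACE", "East Asian", "ASIAN", 200),
    f("a21", "CONF", "ACT", "ACT_RACE", "A", "ASIAN", 500),
    # ---- conforming Native Hawaiian or Other Pacific Islander ----
    f("n1", "CONF", "PCORNET", "PCORNET_RACE", "04", "NHPI", 4000),
    f("n2", "CONF", "TRINETX", "TRINETX_RACE", "Native Hawaiian or Other Pacific Islander", "NHPI", 2217),
    f("n3", "CONF", "OMOP", "OMOP_RACE", "8557", "NHPI", 2000),
    f("n3p", "CONF", "OMOP_PEDSNET", "OMOP_RACE", "8557", "NHPI", 242),
    f("n4", "CONF", "ACT", "ACT_RACE", "2076-8", "NHPI", 1179),
    f("n5", "CONF", "OMOP", "LOCAL_RACE", "Pacific Islander", "NHPI", 1500),
    f("n6", "CONF", "OMOP", "LOCAL_RACE", "Native Hawaiian", "NHPI", 500),
    f("n7", "CONF", "OMOP", "OMOP_RACE", "Guamanian or Chamorro", "NHPI", 100, granular = TRUE),
    f("n8", "CONF", "OMOP", "OMOP_RACE", "Polynesian", "NHPI", 50, granular = TRUE),
    f("n9", "CONF", "OMOP", "CDC_RACE", "2076-8", "NHPI", 429),
    # ---- missing (zero-coded sentinel is the modal form) ----
    f("m1a", "MISSING", "PCORNET", "PCORNET_RACE", "0", "NO_MATCHING_CONCEPT", 150000),
    f("m1b", "MISSING", "ACT", "ACT_RACE", "0", "NO_MATCHING_CONCEPT", 100000),
    f("m1c", "MISSING", "OMOP", "OMOP_RACE", "0", "NO_MATCHING_CONCEPT", 98057),
    f("m2a", "MISSING", "OMOP", "OMOP_RACE", "", "NO_MATCHING_CONCEPT", 116351),
    f("m2b", "MISSING", "TRINETX", "TRINETX_RACE", "", "NO_MATCHING_CONCEPT", 80000),
    f("m2c", "MISSING", "OMOP_PEDSNET", "OMOP_RACE", "", "NO_MATCHING_CONCEPT", 30000),
    f("m2d", "MISSING", "ACT", "ACT_RACE", "", "NO_MATCHING_CONCEPT", 50000),
    f("m3", "MISSING", "OMOP", "LOCAL_RACE", "Null", "NULL_VALUE", 57523),
    f("m4", "MISSING", "OMOP", "LOCAL_RACE", "Unknown", "UNKNOWN", 40000),
    f("m5", "MISSING", "PCORNET", "PCORNET_RACE", "NI", "NO_INFORMATION", 13000),
    # ---- refused ----
    f("r1", "REFUSED", "PCORNET", "PCORNET_RACE", "07", "NO_MATCHING_CONCEPT", 60000),
    f("r2", "REFUSED", "OMOP", "LOCAL_RACE", "Refused", "NO_MATCHING_CONCEPT", 25787),
    f("r3", "REFUSED", "ACT", "ACT_RACE", "Declined", "NO_MATCHING_CONCEPT", 10000),
    f("r4", "REFUSED", "TRINETX", "TRINETX_RACE", "Refused", "NO_MATCHING_CONCEPT", 11658),
    # ---- other ----
    f("o1", "OTHER", "PCORNET", "PCORNET_RACE", "OT", "NO_MATCHING_CONCEPT", 100000),
    f("o2a", "OTHER", "OMOP", "OMOP_RACE", "8522", "OTHER_RACE", 16383),
    f("o2b", "OTHER", "OMOP_PEDSNET", "OMOP_RACE", "8522", "OTHER_RACE", 2855),
    f("o3", "OTHER", "OMOP", "LOCAL_RACE", "Other", "OTHER", 25000),
    f("o4", "OTHER", "ACT", "ACT_RACE", "2131-1", "NO_MATCHING_CONCEPT", 100000),
    f("o5", "OTHER", "TRINETX", "TRINETX_RACE", "Other", "NO_MATCHING_CONCEPT", 20000),
    f("o6", "OTHER", "OMOP", "LOCAL_RACE", "Other Race", "NO_MATCHING_CONCEPT", 42540),
    f("o7", "OTHER", "ACT", "ACT_RACE", "Other", "NO_MATCHING_CONCEPT", 50000),
    # ---- multiracial (true multi-selects plus single multiracial tokens) ----
    f("x1", "MULTIRACIAL", "OMOP", "LOCAL_RACE", "White;Black or African American", "NO_MATCHING_CONCEPT", 1563),
    f("x2", "MULTIRACIAL", "OMOP", "LOCAL_RACE", "White;Asian", "NO_MATCHING_CONCEPT", 2201),
    f("x3", "MULTIRACIAL", "PCORNET", "PCORNET_RACE", "06", "NO_MATCHING_CONCEPT", 44807),
    f("x4", "MULTIRACIAL", "OMOP", "LOCAL_RACE", "Multiple Race", "NO_MATCHING_CONCEPT", 25193),
    f("x5", "MULTIRACIAL", "OMOP", "LOCAL_RACE", "Two or More Races", "NO_MATCHING_CONCEPT", 15215),
    f("x6", "MULTIRACIAL", "OMOP", "LOCAL_RACE", "Multiracial", "NO_MATCHING_CONCEPT", 10000),
    # ---- misclassified (source resolves, harmonization went elsewhere) ----
    f("c1", "MISCLASSIFIED", "OMOP", "LOCAL_RACE", "Black", "BLACK_UNMAPPED", 18885),
    f("c2", "MISCLASSIFIED", "OMOP", "LOCAL_RACE", "Black", "NO_MATCHING_CONCEPT", 530),
    f("c3", "MISCLASSIFIED", "OMOP", "LOCAL_RACE", "Hispanic", "NO_MATCHING_CONCEPT", 11728),
    f("c4", "MISCLASSIFIED", "OMOP", "LOCAL_RACE", "Caucasian", "NO_MATCHING_CONCEPT", 6557),
    f("c5", "MISCLASSIFIED", "OMOP", "LOCAL_RACE", "Pacific Islander", "NO_MATCHING_CONCEPT", 3067),
    f("c6", "MISCLASSIFIED", "OMOP", "LOCAL_RACE", "Asian", "NO_MATCHING_CONCEPT", 1850),
    # ---- uninterpretable (both TriNetX; "^" is a placeholder for the
    #      second undecipherable encoding) ----
    f("u1", "UNINTERPRETABLE", "TRINETX", "TRINETX_RACE", "@", "NO_MATCHING_CONCEPT", 2000),
    f("u2", "UNINTERPRETABLE", "TRINETX", "TRINETX_RACE", "^", "NO_MATCHING_CONCEPT", 268),
    # ---- more granular (never rolled up; all OMOP sites) ----
    f("g1", "MORE_GRANULAR", "OMOP", "OMOP_RACE", "Asian Indian", "ASIAN_INDIAN", 1234, granular = TRUE),
    f("g2", "MORE_GRANULAR", "OMOP", "OMOP_RACE", "38003574", "ASIAN_INDIAN", 300, granular = TRUE),
    f("g3", "MORE_GRANULAR", "OMOP", "OMOP_RACE", "Filipino", "FILIPINO", 300, granular = TRUE),
    f("g4", "MORE_GRANULAR", "OMOP", "OMOP_RACE", "Chinese", "CHINESE", 250, granular = TRUE),
    f("g5", "MORE_GRANULAR", "OMOP", "OMOP_RACE", "Korean", "KOREAN", 150, granular = TRUE),
    f("g6", "MORE_GRANULAR", "OMOP", "OMOP_RACE", "Vietnamese", "VIETNAMESE", 130, granular = TRUE),
    f("g7", "MORE_GRANULAR", "OMOP", "OMOP_RACE", "Japanese", "JAPANESE", 63, granular = TRUE),
    f("g8", "MORE_GRANULAR", "OMOP", "OMOP_RACE", "Guamanian or Chamorro", "GUAMANIAN_CHAMORRO", 30, granular = TRUE),
    f("g9", "MORE_GRANULAR", "OMOP", "OMOP_RACE", "Polynesian", "POLYNESIAN", 20, granular = TRUE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# 56 sites in 10 reporting schemas: 41 standard-adherent, 5 with additional
# granular categories, 10 omitting at least one category, 51 with a separate
# ethnicity field.  cats are comma-joined main-concept ids.
fixture_sites <- function() {
  s <- function(site_id, model, cats, eth, bulk = FALSE, grn = FALSE)
    data.frame(site_id = site_id, model = model, cats = cats, eth = eth,
               bulk = bulk, grn = grn, stringsAsFactors = FALSE)
  all4 <- "WHITE,BLACK_AA,ASIAN,NHPI"
  rows <- c(
    lapply(1:20, function(i) s(sprintf("OMOP-%02d", i), "OMOP", all4, TRUE, bulk = i == 1)),
    lapply(1:10, function(i) s(sprintf("PCOR-%02d", i), "PCORNET", all4, TRUE, bulk = i == 1)),
    lapply(1:4, function(i) s(sprintf("ACT-%02d", i), "ACT", all4, TRUE, bulk = i == 1)),
    lapply(1:4, function(i) s(sprintf("TNX-%02d", i), "TRINETX", all4, TRUE, bulk = i == 1)),
    lapply(1:3, function(i) s(sprintf("PED-%02d", i), "OMOP_PEDSNET", all4, TRUE, bulk = i == 1)),
    lapply(1:5, function(i) s(sprintf("GRN-%02d", i), "OMOP", all4, TRUE, grn = TRUE)),
    list(s("OMIT-01", "OMOP", "WHITE,BLACK_AA,ASIAN", TRUE),
         s("OMIT-02", "OMOP", "WHITE,BLACK_AA,ASIAN", TRUE),
         s("OMIT-03", "OMOP", "WHITE,BLACK_AA,NHPI", TRUE),
         s("OMIT-04", "OMOP", "WHITE,ASIAN,NHPI", TRUE),
         s("OMIT-05", "OMOP", "WHITE,BLACK_AA", TRUE),
         s("OMIT-06", "OMOP", "WHITE,BLACK_AA,ASIAN", FALSE),
         s("OMIT-07", "OMOP", "WHITE,BLACK_AA,ASIAN", FALSE),
         s("OMIT-08", "OMOP", "WHITE,BLACK_AA", FALSE),
         s("OMIT-09", "OMOP", "WHITE", FALSE),
         s("OMIT-10", "OMOP", "WHITE,NHPI", FALSE)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ethnicity encodings per data model and bucket
fixture_eth_fields <- function(model, bucket) {
  if (bucket == "NONE") return(c("", "", ""))
  sys <- switch(model, OMOP = "OMOP_ETH", OMOP_PEDSNET = "OMOP_ETH",
                PCORNET = "PCORNET_ETH", ACT = "ACT_ETH", TRINETX = "TRINETX_ETH")
  val <- switch(bucket,
                HL = switch(model, OMOP = "38003563", OMOP_PEDSNET = "38003563",
                            PCORNET = "Y", ACT = "2135-2", TRINETX = "Hispanic or Latino"),
                NHL = switch(model, OMOP = "38003564", OMOP_PEDSNET = "38003564",
                             PCORNET = "N", ACT = "2186-5", TRINETX = "Not Hispanic or Latino"),
                MISS = switch(model, OMOP = "", OMOP_PEDSNET = "",
                              PCORNET = "NI", ACT = "NI", TRINETX = ""))
  h <- switch(bucket, HL = "HISPANIC", NHL = "NOT_HISPANIC",
              MISS = switch(model, PCORNET = "NO_INFORMATION", ACT = "NO_INFORMATION",
                            "NO_MATCHING_CONCEPT"))
  c(sys, val, h)
}

#' Deterministic weighted fixture of the N3C data-quality marginals
#'
#' Builds, with no randomness, a weighted aggregate cohort (a few hundred
#' rows standing for 6,513,464 patients at 56 sites) whose audit under the
#' standard pipeline reproduces the published N3C race/ethnicity
#' conformance marginals exactly: 79.3\% conforming race, the seven
#' nonconformance category counts, the misclassification breakdown, the
#' ethnicity cross-cells, the per-data-model conformance strata, the
#' distinct-encoding counts (21/24/22 for White / Black or African American
#' / Asian) and the 10 site reporting schemas.  Cross-cells the source
#' tables do not print are fixed at plausible values and never asserted.
#'
#' @return a record data.frame ready for \code{\link{audit}} (upstream
#'   mode).
#' @export
#' @examples
#' fx <- n3c_fixture()
#' sum(fx$weight)  # 6,513,464
n3c_fixture <- function() {
  rows <- fixture_base_rows()
  sites <- fixture_sites()
  rows$site <- NA_character_
  rows$forced <- FALSE
  rows$eth_fixed <- NA_character_

  # seed rows so that every site exhibits its configured reporting schema
  seed_w <- c(WHITE = 20, BLACK_AA = 10, ASIAN = 5, NHPI = 2)
  seed_src <- c(OMOP.WHITE = "w5", OMOP.BLACK_AA = "b3", OMOP.ASIAN = "a3", OMOP.NHPI = "n3",
                PCORNET.WHITE = "w1", PCORNET.BLACK_AA = "b1", PCORNET.ASIAN = "a1", PCORNET.NHPI = "n1",
                ACT.WHITE = "w7", ACT.BLACK_AA = "b5", ACT.ASIAN = "a5", ACT.NHPI = "n4",
                TRINETX.WHITE = "w3", TRINETX.BLACK_AA = "b2", TRINETX.ASIAN = "a2", TRINETX.NHPI = "n2",
                OMOP_PEDSNET.WHITE = "w5p", OMOP_PEDSNET.BLACK_AA = "b3p",
                OMOP_PEDSNET.ASIAN = "a3p", OMOP_PEDSNET.NHPI = "n3p")
  seeds <- list()
  for (i in seq_len(nrow(sites))) {
    st <- sites[i, ]
    if (st$bulk) next
    for (cat in strsplit(st$cats, ",")[[1]]) {
      src_id <- seed_src[[paste(st$model, cat, sep = ".")]]
      j <- which(rows$id == src_id)
      rows$weight[j] <- rows$weight[j] - seed_w[[cat]]
      sr <- rows[j, ]
      sr$weight <- seed_w[[cat]]
      sr$site <- st$site_id
      sr$forced <- !st$eth
      sr$id <- paste0(src_id, "@", st$site_id)
      seeds[[length(seeds) + 1L]] <- sr
    }
  }
  stopifnot(all(rows$weight > 0))

  # granular-source rows live at the five granular-extended sites
  bulk_site <- stats::setNames(sites$site_id[sites$bulk], sites$model[sites$bulk])
  grn_sites <- sites$site_id[sites$grn]
  gi <- which(rows$granular)
  rows$site[gi] <- grn_sites[((seq_along(gi) - 1L) %% length(grn_sites)) + 1L]
  rest <- which(!rows$granular)
  rows$site[rest] <- unname(bulk_site[rows$model[rest]])
  rows <- rbind(rows, do.call(rbind, seeds))

  # carve granular-ethnicity detail out of the OMOP White bulk stratum
  j <- which(rows$id == "w5")
  gran_eth <- c("Puerto Rican" = 500, "Mexican" = 700, "Cuban" = 300,
                "South American" = 200, "Central American" = 150,
                "Dominican" = 100, "Spaniard" = 50)
  rows$weight[j] <- rows$weight[j] - sum(gran_eth)
  ge <- rows[rep(j, length(gran_eth)), ]
  ge$weight <- unname(gran_eth)
  ge$eth_fixed <- names(gran_eth)
  ge$id <- paste0("w5e", seq_along(gran_eth))
  rows <- rbind(rows, ge)
  rownames(rows) <- NULL

  # ---- ethnicity allocation ----
  rows$hl <- 0; rows$miss <- 0; rows$locked <- FALSE
  rows$locked[rows$forced] <- TRUE
  rows$miss[rows$forced] <- rows$weight[rows$forced]
  fixed <- !is.na(rows$eth_fixed)
  rows$hl[fixed] <- rows$weight[fixed]
  rows$locked[fixed] <- TRUE
  # the Hispanic-in-race stratum's own ethnicity column: 2,258 marked
  # Not Hispanic or Latino, the rest Hispanic or Latino
  j <- which(rows$id == "c3"); rows$hl[j] <- 9470; rows$locked[j] <- TRUE
  j <- which(rows$id == "c1"); rows$hl[j] <- 3033; rows$locked[j] <- TRUE

  hl_targets <- c(CONF = 371864, MISSING = 99853, OTHER = 217476,
                  REFUSED = 22683, MULTIRACIAL = 46916,
                  UNINTERPRETABLE = 300, MORE_GRANULAR = 100)
  for (cat in names(hl_targets)) {
    need <- hl_targets[[cat]]
    for (i in which(rows$category == cat & !rows$locked)) {
      if (need == 0) break
      take <- min(need, rows$weight[i])
      rows$hl[i] <- take
      need <- need - take
    }
    stopifnot(need == 0)
  }
  miss_budget <- c(OMOP = 634925, PCORNET = 159502, ACT = 262875,
                   TRINETX = 0, OMOP_PEDSNET = 0)
  miss_budget[["OMOP"]] <- miss_budget[["OMOP"]] - sum(rows$miss[rows$forced])
  for (mm in names(miss_budget)) {
    need <- miss_budget[[mm]]
    for (i in which(rows$model == mm & !rows$locked)) {
      if (need == 0) break
      take <- min(need, rows$weight[i] - rows$hl[i])
      rows$miss[i] <- take
      need <- need - take
    }
    stopifnot(need == 0)
  }
  rows$nhl <- rows$weight - rows$hl - rows$miss
  stopifnot(all(rows$nhl >= 0))

  # ---- explode into records ----
  out <- list()
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    parts <- c(HL = r$hl, NHL = r$nhl, MISS = r$miss)
    parts <- parts[parts > 0]
    if (r$forced) parts <- c(NONE = r$weight)
    for (bk in names(parts)) {
      ef <- if (!is.na(r$eth_fixed)) c("OMOP_ETH", r$eth_fixed, "HISPANIC")
            else fixture_eth_fields(r$model, bk)
      out[[length(out) + 1L]] <- data.frame(
        patient_id = sprintf("%s.%s", r$id, bk),
        site_id = r$site, data_model = r$model,
        race_system = r$system, race_value = r$value,
        ethnicity_system = ef[1], ethnicity_value = ef[2],
        harmonized_race = r$hrace, harmonized_ethnicity = ef[3],
        weight = unname(parts[[bk]]), stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, out)
  rownames(rec) <- NULL

  # internal consistency of the construction
  stopifnot(sum(rec$weight) == 6513464,
            sum(rows$hl) == 773695,
            sum(rows$miss) == 1057302,
            sum(rows$weight[rows$category == "CONF"]) == 5167969,
            sum(rows$weight[rows$hrace == "NO_MATCHING_CONCEPT"]) == 1169372)
  validate_records(rec)
}
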