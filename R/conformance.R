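# Conformance classification: conforming vs a seven-way nonconformance
# taxonomy, plus the optional AI/AN redaction policy.

#' Classify race conformance
#'
#' A record's race is \emph{conforming} when its harmonized main race concept
#' is one of the 5 OMB minimum categories.  Every other record receives
#' exactly one taxonomy category, assigned by precedence:
#' \enumerate{
#'   \item \code{MISSING} — no race value, or every value is a missing/unknown
#'     sentinel (synonym group or flag such as \code{NULL_VALUE});
#'   \item \code{REFUSED} — any value is a refusal ("Refused", "Declined",
#'     PCORnet \code{07}, ...);
#'   \item \code{OTHER} — any value resolves to the deprecated "Other" /
#'     "Other race" flags;
#'   \item \code{MULTIRACIAL} — a multi-select with two or more distinct main
#'     concepts, or a single multiracial token ("Two or more races", ...);
#'   \item \code{MORE_GRANULAR} — the harmonized concept is a granular
#'     subcategory that was never rolled up;
#'   \item \code{MISCLASSIFIED} — the source value resolves to a main race
#'     concept (subtype \code{WRONG_TARGET}) or to Hispanic/Latino on the
#'     race axis (subtype \code{ETHNICITY_IN_RACE}), yet the harmonized
#'     concept differs;
#'   \item \code{UNINTERPRETABLE} — residual (e.g. a bare \code{"@"}).
#' }
#' The precedence resolves overlaps toward the more specific data-collection
#' phenomenon and is configurable.
#'
#' @param registry an \code{re_registry}.
#' @param result output of \code{\link{harmonize_records}}.
#' @param precedence character vector ordering the seven categories.
#' @return data.frame with \code{race_status} (\code{CONFORMING} /
#'   \code{NONCONFORMING}), \code{race_category} (one of the seven, or
#'   \code{""}), and \code{misclass_subtype} (\code{WRONG_TARGET},
#'   \code{ETHNICITY_IN_RACE}, or \code{""}).
#' @export
classify_race <- function(registry, result, precedence = CLASSIFY_PRECEDENCE) {
  stopifnot(inherits(registry, "re_registry"), is.data.frame(result))
  if (!setequal(precedence, NONCONF_CATEGORIES))
    abort_config("precedence must be a permutation of the seven taxonomy categories")
  n <- nrow(result)
  conforming <- result$race_main %in% RACE_MAINS
  rules <- list(
    MISSING = result$n_values == 0L | result$all_missing_tok,
    REFUSED = result$any_refused_tok,
    OTHER = result$any_other_tok,
    MULTIRACIAL = result$n_distinct_mains >= 2L | result$any_multi_tok,
    MORE_GRANULAR = result$race_main_level == "GRANULAR",
    MISCLASSIFIED = !is.na(result$source_main) | result$any_hispanic_in_race,
    UNINTERPRETABLE = rep(TRUE, n))
  category <- rep("", n)
  open <- !conforming
  for (cat in c(precedence[precedence != "UNINTERPRETABLE"], "UNINTERPRETABLE")) {
    hit <- open & rules[[cat]]
    category[hit] <- cat
    open <- open & !hit
  }
  subtype <- rep("", n)
  mis <- category == "MISCLASSIFIED"
  subtype[mis] <- ifelse(!is.na(result$source_main[mis]), "WRONG_TARGET", "ETHNICITY_IN_RACE")
  data.frame(race_status = ifelse(conforming, "CONFORMING", "NONCONFORMING"),
             race_category = category, misclass_subtype = subtype,
             stringsAsFactors = FALSE)
}

#' Classify ethnicity conformance
#'
#' Ethnicity conforms when the harmonized ethnicity is one of the two
#' standard categories (Hispanic or Latino / Not Hispanic or Latino);
#' nonconforming ethnicity is not subdivided further.
#'
#' @param registry an \code{re_registry}.
#' @param result output of \code{\link{harmonize_records}}.
#' @return character vector (\code{CONFORMING} / \code{NONCONFORMING}).
#' @export
classify_ethnicity <- function(registry, result) {
  ifelse(result$ethnicity_main %in% ETH_MAINS, "CONFORMING", "NONCONFORMING")
}

#' Construct a redaction policy
#'
#' Emulates an enclave-side policy that obscures a protected group by
#' aggregating its records into a flag category (as done for American Indian
#' or Alaska Native patients, folded into "Other").
#'
#' @param enabled apply the policy?
#' @param target_concepts concept ids to redact (default AI/AN).
#' @param redirect_to flag concept receiving the redacted records.
#' @return a \code{redaction_policy} list.
#' @export
redaction_policy <- function(enabled = FALSE, target_concepts = "AIAN",
                             redirect_to = "OTHER") {
  structure(list(enabled = isTRUE(enabled),
                 target_concepts = as.character(target_concepts),
                 redirect_to = as.character(redirect_to)),
            class = "redaction_policy")
}

#' Apply a redaction policy to classified records
#'
#' When enabled, every record whose harmonized race is in the target set is
#' re-labelled \code{NONCONFORMING}/\code{OTHER} with its race main set to
#' the redirect flag.  Total weight is conserved; the redacted weight is
#' recorded in the \code{redaction_count} attribute.
#'
#' @param policy a \code{\link{redaction_policy}}.
#' @param audited data.frame of classified records (see \code{\link{audit}}).
#' @param registry an \code{re_registry} (validates the redirect flag).
#' @return the audited data.frame, with attribute \code{redaction_count}.
#' @export
apply_redaction <- function(policy, audited, registry) {
  stopifnot(inherits(policy, "redaction_policy"))
  if (!policy$enabled) {
    attr(audited, "redaction_count") <- 0
    return(audited)
  }
  lev <- registry$maps$level[policy$redirect_to]
  if (is.na(lev) || lev != "FLAG")
    abort_config("redaction redirect_to must be a registered FLAG concept")
  hit <- audited$race_main %in% policy$target_concepts
  audited$race_main[hit] <- policy$redirect_to
  audited$race_status[hit] <- "NONCONFORMING"
  audited$race_category[hit] <- "OTHER"
  audited$misclass_subtype[hit] <- ""
  attr(audited, "redaction_count") <- sum(audited$weight[hit])
  audited
}
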