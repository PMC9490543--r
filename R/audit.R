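# Main entry point: the audit pipeline as a single classed object.

#' Audit race and ethnicity conformance in a demographic extract
#'
#' Runs the full pipeline — harmonization (or verbatim adoption of the
#' upstream harmonization), conformance classification into the seven-way
#' nonconformance taxonomy, optional redaction, and weighted report
#' aggregation — and returns a classed object with \code{print} and
#' \code{summary} methods.
#'
#' @param records a record data.frame (from \code{\link{read_records}},
#'   \code{\link{generate_cohort}} or \code{\link{n3c_fixture}}).
#' @param registry an \code{re_registry}; defaults to the shipped
#'   terminology.
#' @param mode harmonization provenance: \code{"upstream"} (default; audit
#'   the delivered mapping, recomputing where absent), \code{"recompute"},
#'   or \code{"both"}.
#' @param redact a \code{\link{redaction_policy}}; disabled by default.
#' @param delimiters multi-select delimiters.
#' @param strict strict noise handling (see \code{\link{harmonize_records}}).
#' @param precedence taxonomy precedence (see \code{\link{classify_race}}).
#' @return an object of class \code{re_audit}: \code{$records} (per-record
#'   audit table), \code{$report} (weighted aggregates, an
#'   \code{re_report}), plus run metadata.
#' @export
#' @examples
#' aud <- audit(n3c_fixture())
#' aud
audit <- function(records, registry = load_registry(),
                  mode = c("upstream", "recompute", "both"),
                  redact = redaction_policy(FALSE),
                  delimiters = DEFAULT_DELIMITERS, strict = FALSE,
                  precedence = CLASSIFY_PRECEDENCE) {
  mode <- match.arg(mode)
  records <- validate_records(records)
  harm <- harmonize_records(registry, records, mode = mode,
                            delimiters = delimiters, strict = strict)
  cls <- classify_race(registry, harm, precedence = precedence)
  eth_status <- classify_ethnicity(registry, harm)
  audited <- cbind(records,
                   harm[, c("race_concepts", "race_main", "race_main_recomputed",
                            "ethnicity_main", "ethnicity_main_recomputed",
                            "provenance_race", "provenance_ethnicity",
                            "n_values", "n_distinct_mains", "source_main",
                            "any_hispanic_in_race", "any_granular_source")],
                   cls)
  audited$ethnicity_status <- eth_status
  audited <- apply_redaction(redact, audited, registry)
  redaction_count <- attr(audited, "redaction_count")
  report <- summarize_audit(audited, registry, redaction_count)
  structure(list(records = audited, report = report, registry = registry,
                 mode = mode, redaction = redact,
                 harmonize_log = attr(harm, "harmonize_log")),
            class = "re_audit")
}

#' @export
print.re_audit <- function(x, ...) {
  r <- x$report
  cat("<re_audit>  mode:", x$mode, " registry v", x$registry$version, "\n", sep = "")
  cat(sprintf("  records: %d rows, total weight %s\n",
              nrow(x$records), format(r$total_weight, big.mark = ",")))
  fmt <- function(f) if (is.na(f)) "undefined" else sprintf("%.1f%%", pct_round(f))
  cat(sprintf("  race conforming:      %s (%s)\n",
              fmt(safe_frac(r$race_conforming_weight, r$total_weight)),
              format(r$race_conforming_weight, big.mark = ",")))
  cat(sprintf("  ethnicity conforming: %s (%s)\n",
              fmt(safe_frac(r$ethnicity_conforming_weight, r$total_weight)),
              format(r$ethnicity_conforming_weight, big.mark = ",")))
  if (r$redaction_count > 0)
    cat(sprintf("  redacted weight: %s\n", format(r$redaction_count, big.mark = ",")))
  invisible(x)
}

#' @export
summary.re_audit <- function(object, ...) {
  structure(list(report = object$report, mode = object$mode), class = "summary.re_audit")
}

#' @export
print.summary.re_audit <- function(x, ...) {
  r <- x$report
  cat("Race/ethnicity conformance audit (mode:", x$mode, ")\n\n")
  cat(sprintf("Total weight: %s\n", format(r$total_weight, big.mark = ",")))
  cat(sprintf("Race conforming:      %s  (%.1f%%)\n",
              format(r$race_conforming_weight, big.mark = ","),
              pct_round(safe_frac(r$race_conforming_weight, r$total_weight))))
  cat(sprintf("Ethnicity conforming: %s  (%.1f%%)\n\n",
              format(r$ethnicity_conforming_weight, big.mark = ","),
              pct_round(safe_frac(r$ethnicity_conforming_weight, r$total_weight))))
  cat("Nonconformance taxonomy (race):\n")
  cw <- unlist(r$race_category_weights)
  nc <- sum(cw)
  for (k in names(cw)) {
    cat(sprintf("  %-16s %12s  (%s%% of nonconforming)\n", k,
                format(cw[[k]], big.mark = ","),
                ifelse(nc > 0, format(pct_round(cw[[k]] / nc), nsmall = 1), "NA")))
  }
  cat("\nTop harmonized race concepts:\n")
  top <- utils::head(sort(unlist(r$concept_weights), decreasing = TRUE), 10)
  for (k in names(top))
    cat(sprintf("  %-24s %12s\n", r$concept_displays[[k]] %||% k,
                format(top[[k]], big.mark = ",")))
  invisible(x)
}
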