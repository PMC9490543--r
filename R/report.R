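# Weighted report aggregation and the standard audit tabulations.

summarize_audit <- function(audited, registry, redaction_count = 0) {
  w <- audited$weight
  total <- sum(w)
  concept_weights <- wt_sum(w, audited$race_main)
  concept_weights <- sort(concept_weights, decreasing = TRUE)
  race_conf <- sum(w[audited$race_status == "CONFORMING"])
  catw <- stats::setNames(numeric(length(NONCONF_CATEGORIES)), NONCONF_CATEGORIES)
  got <- wt_sum(w[audited$race_status == "NONCONFORMING"],
                audited$race_category[audited$race_status == "NONCONFORMING"])
  catw[names(got)] <- got
  eth_conf <- sum(w[audited$ethnicity_status == "CONFORMING"])

  per_model <- conformance_by_model_df(audited)
  schemas <- detect_site_schemas_df(audited)

  structure(list(
    total_weight = total,
    concept_weights = as.list(concept_weights),
    concept_displays = as.list(concept_display(registry, names(concept_weights))) |>
      stats::setNames(names(concept_weights)),
    race_conforming_weight = race_conf,
    race_category_weights = as.list(catw),
    ethnicity_conforming_weight = eth_conf,
    race_conforming_pct = pct_round(safe_frac(race_conf, total)),
    ethnicity_conforming_pct = pct_round(safe_frac(eth_conf, total)),
    per_model = per_model,
    site_schemas = schemas,
    n_schemas = attr(schemas, "n_schemas"),
    redaction_count = redaction_count %||% 0), class = "re_report")
}

audited_records <- function(x) {
  if (inherits(x, "re_audit")) x$records
  else if (is.data.frame(x) && "race_status" %in% names(x)) x
  else abort_config("expected an re_audit object or an audited record data.frame")
}

eth_dimension <- function(audited) {
  ifelse(audited$ethnicity_main == "HISPANIC", "Hispanic or Latino",
         ifelse(audited$ethnicity_main == "NOT_HISPANIC", "Not Hispanic or Latino",
                "Nonconforming"))
}

#' Weighted cross-tabulation of the audit
#'
#' Cross-tabulates record weight with the nonconformance taxonomy (or the
#' conforming/nonconforming split) on the rows against ethnicity, data model
#' or site on the columns.  Cell weights sum to the row margins; per-row
#' fractions are attached.
#'
#' @param x an \code{re_audit} (or its \code{$records}).
#' @param row \code{"race_category"} (conforming + the seven categories) or
#'   \code{"conformance"}.
#' @param col \code{"ethnicity"}, \code{"data_model"} or \code{"site"}.
#' @return a weight matrix with attribute \code{row_fractions}.
#' @export
#' @examples
#' ct <- crosstab(audit(n3c_fixture()), "race_category", "ethnicity")
#' attr(ct, "row_fractions")["OTHER", "Hispanic or Latino"]
crosstab <- function(x, row = c("race_category", "conformance"),
                     col = c("ethnicity", "data_model", "site")) {
  aud <- audited_records(x)
  if (!row[1] %in% c("race_category", "conformance") ||
      !col[1] %in% c("ethnicity", "data_model", "site"))
    abort_config("unknown crosstab dimension: row=%s col=%s", row[1], col[1])
  row <- match.arg(row); col <- match.arg(col)
  rv <- switch(row,
               race_category = ifelse(aud$race_status == "CONFORMING",
                                      "CONFORMING", aud$race_category),
               conformance = aud$race_status)
  cv <- switch(col,
               ethnicity = eth_dimension(aud),
               data_model = aud$data_model,
               site = aud$site_id)
  tab <- stats::xtabs(weight ~ rv + cv,
                      data = data.frame(weight = aud$weight, rv = rv, cv = cv))
  m <- as.matrix(tab)
  names(dimnames(m)) <- c(row, col)
  fr <- m / ifelse(rowSums(m) == 0, NA, rowSums(m))
  attr(m, "row_fractions") <- fr
  m
}

conformance_by_model_df <- function(aud) {
  models <- sort(unique(aud$data_model))
  out <- do.call(rbind, lapply(models, function(mm) {
    s <- aud[aud$data_model == mm, ]
    tw <- sum(s$weight)
    rc <- sum(s$weight[s$race_status == "CONFORMING"])
    ec <- sum(s$weight[s$ethnicity_status == "CONFORMING"])
    data.frame(data_model = mm, total_weight = tw,
               race_conforming = rc, race_fraction = safe_frac(rc, tw),
               ethnicity_conforming = ec, ethnicity_fraction = safe_frac(ec, tw),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-data-model conformance fractions
#'
#' @param x an \code{re_audit} (or its \code{$records}).
#' @return data.frame with one row per data model present in the input
#'   (absent models are omitted) and race/ethnicity conforming fractions.
#' @export
conformance_by_model <- function(x) conformance_by_model_df(audited_records(x))

detect_site_schemas_df <- function(aud) {
  sites <- sort(unique(aud$site_id))
  out <- do.call(rbind, lapply(sites, function(s) {
    ss <- aud[aud$site_id == s, ]
    cats <- sort(unique(ss$race_main[ss$race_status == "CONFORMING" &
                                       ss$race_main %in% RACE_MAINS]))
    gran <- any(ss$any_granular_source | ss$race_category == "MORE_GRANULAR")
    eth <- any(nzchar(ss$ethnicity_system) | nzchar(ss$ethnicity_value) |
                 nzchar(ss$harmonized_ethnicity))
    data.frame(site_id = s, data_model = ss$data_model[1],
               categories = paste(cats, collapse = ","),
               has_granular = gran, has_ethnicity_field = eth,
               stringsAsFactors = FALSE)
  }))
  key <- paste(out$categories, out$has_granular, out$has_ethnicity_field, sep = "|")
  out$schema_id <- match(key, unique(key))
  attr(out, "n_schemas") <- length(unique(key))
  rownames(out) <- NULL
  out
}

#' Detect per-site reporting schemas
#'
#' A site's reporting schema is the set of main race categories it actually
#' reports (conforming records), whether it emits granular subcategories,
#' and whether ethnicity exists as a separate field.  The distinct-schema
#' count is the number of unique such combinations.
#'
#' @param x an \code{re_audit} (or its \code{$records}).
#' @return data.frame, one row per site, with attribute \code{n_schemas}.
#' @export
detect_site_schemas <- function(x) detect_site_schemas_df(audited_records(x))

#' Compare the audited distribution against reference tables
#'
#' Aligns the audit's race/ethnicity distribution (main-category weights over
#' total weight, plus the Hispanic or Latino share) with user-supplied
#' reference fraction tables (e.g. census estimates).  Categories missing
#' from a reference are marked not applicable (\code{NA}).  No data are
#' downloaded; references must be supplied by the caller.
#'
#' @param x an \code{re_audit}.
#' @param references named list of named numeric vectors; names are category
#'   displays (e.g. \code{"White"}), values are fractions in \[0, 1\].
#' @return data.frame: one row per category, the audit fraction, one column
#'   per reference, and per-reference absolute differences.
#' @export
compare_distributions <- function(x, references) {
  stopifnot(inherits(x, "re_audit"), is.list(references))
  r <- x$report
  for (nm in names(references)) {
    v <- references[[nm]]
    if (!is.numeric(v) || is.null(names(v)) || any(v < 0 | v > 1, na.rm = TRUE))
      abort_config("reference '%s' must be a named numeric vector of fractions in [0,1]", nm)
  }
  cats <- c(stats::setNames(concept_display(x$registry, RACE_MAINS), RACE_MAINS),
            HISPANIC = "Hispanic or Latino")
  eth_hl <- sum(x$records$weight[x$records$ethnicity_main == "HISPANIC"])
  frac <- vapply(names(cats), function(cid) {
    if (cid == "HISPANIC") safe_frac(eth_hl, r$total_weight)
    else safe_frac(r$concept_weights[[cid]] %||% 0, r$total_weight)
  }, numeric(1))
  out <- data.frame(category = unname(cats), audit_fraction = unname(frac),
                    stringsAsFactors = FALSE)
  for (nm in names(references)) {
    ref <- references[[nm]][out$category]
    out[[nm]] <- unname(ref)
    out[[paste0("diff_", nm)]] <- abs(out$audit_fraction - unname(ref))
  }
  out
}

#' Serialize an audit report to JSON
#'
#' Writes the report as a single stable JSON document (fixed key order,
#' fixed numeric formatting) so that identical inputs yield byte-identical
#' output.
#'
#' @param x an \code{re_audit}.
#' @param path optional output file.
#' @return the JSON string, invisibly if \code{path} is given.
#' @export
report_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "re_audit"))
  r <- x$report
  ct <- crosstab(x, "race_category", "ethnicity")
  pm <- r$per_model
  doc <- list(
    schema_version = "1.0",
    registry_version = x$registry$version,
    mode = x$mode,
    total_weight = r$total_weight,
    race_conforming_weight = r$race_conforming_weight,
    race_conforming_pct = r$race_conforming_pct,
    ethnicity_conforming_weight = r$ethnicity_conforming_weight,
    ethnicity_conforming_pct = r$ethnicity_conforming_pct,
    race_category_weights = r$race_category_weights,
    concept_weights = r$concept_weights,
    ethnicity_crosstab = apply(ct, 1, as.list, simplify = FALSE),
    per_model = lapply(seq_len(nrow(pm)), function(i) as.list(pm[i, ])),
    n_site_schemas = r$n_schemas,
    n_sites = nrow(r$site_schemas),
    redaction_count = r$redaction_count)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  if (!is.null(path)) {
    writeLines(js, path, useBytes = TRUE)
    return(invisible(js))
  }
  js
}
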