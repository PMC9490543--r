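# Ingestion of demographic extracts.

RECORD_COLUMNS <- c("patient_id", "site_id", "data_model", "race_system",
                    "race_value", "ethnicity_system", "ethnicity_value",
                    "harmonized_race", "harmonized_ethnicity", "weight")
MANDATORY_COLUMNS <- c("site_id", "data_model", "race_system", "race_value")
DEFAULT_DELIMITERS <- c(";", "|", ",")

#' Split a multi-select race string into value tokens
#'
#' Sites that let patients select several races often report the selections
#' in a single column.  Splits on any configured delimiter, normalizes each
#' token, drops empty tokens, and preserves order and duplicates.  A total
#' function: any string (including \code{""}) yields a character vector.
#'
#' @param raw character vector of raw strings.
#' @param delimiters character vector of single-character delimiters.
#' @return a list of character vectors (one per input element).
#' @export
#' @examples
#' parse_multiselect("White;Black or African American")
#' parse_multiselect("White;;White")
parse_multiselect <- function(raw, delimiters = DEFAULT_DELIMITERS) {
  stopifnot(is.character(delimiters), all(nchar(delimiters) == 1L))
  rx <- paste0("[", paste0("\\", delimiters, collapse = ""), "]")
  raw <- as.character(raw)
  raw[is.na(raw)] <- ""
  toks <- strsplit(raw, rx)
  lapply(toks, function(t) {
    t <- normalize_value(t)
    t[nzchar(t)]
  })
}

#' Read a demographic extract
#'
#' Reads a delimited text file with a documented header into one record per
#' row.  Unknown columns are ignored; missing optional columns are filled
#' with defaults (\code{weight = 1}, empty strings elsewhere).  Row numbers
#' are preserved for error reporting, and a read log (row counts, rejected
#' rows) is attached as an attribute.
#'
#' @param path CSV (or TSV) file; the delimiter is inferred from the
#'   extension unless \code{sep} is given.
#' @param sep field separator; default inferred (\code{"\\t"} for
#'   \code{.tsv}, otherwise \code{","}).
#' @return data.frame of records with the canonical column set and
#'   attribute \code{read_log}.
#' @export
read_records <- function(path, sep = NULL) {
  if (!file.exists(path)) abort_config("input file not found: %s", path)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", check.names = TRUE,
                          encoding = "UTF-8", stringsAsFactors = FALSE,
                          comment.char = "", na.strings = NULL)
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(df))
  if (length(missing_cols))
    abort_config("schema error in %s: missing mandatory column(s): %s",
                 path, paste(missing_cols, collapse = ", "))
  out <- data.frame(row = seq_len(nrow(df)), stringsAsFactors = FALSE)
  for (cc in setdiff(RECORD_COLUMNS, "weight"))
    out[[cc]] <- if (cc %in% names(df)) df[[cc]] else rep("", nrow(df))
  if ("weight" %in% names(df)) {
    w <- suppressWarnings(as.numeric(df$weight))
    bad <- which(is.na(w) | w < 1 | w != floor(w))
    if (length(bad))
      abort_config("row error in %s: non-positive or non-integer weight at row(s): %s",
                   path, paste(utils::head(bad, 10), collapse = ", "))
    out$weight <- w
  } else {
    out$weight <- rep(1, nrow(df))
  }
  out <- validate_records(out)
  attr(out, "read_log") <- list(path = path, rows_read = nrow(df),
                                rows_kept = nrow(out), total_weight = sum(out$weight))
  out
}

# field-level invariants shared by read_records and the generators
validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  for (cc in setdiff(RECORD_COLUMNS, "weight")) {
    if (is.null(records[[cc]])) records[[cc]] <- rep("", nrow(records))
    records[[cc]] <- as.character(records[[cc]])
    records[[cc]][is.na(records[[cc]])] <- ""
  }
  if (is.null(records$weight)) records$weight <- rep(1, nrow(records))
  if (any(records$weight < 1)) abort_config("record weights must be >= 1")
  if (any(!nzchar(records$site_id))) abort_config("site_id must be nonempty")
  bad_model <- setdiff(unique(records$data_model), DATA_MODELS)
  if (length(bad_model))
    abort_config("unknown data model(s): %s", paste(bad_model, collapse = ", "))
  if (is.null(records$row)) records$row <- seq_len(nrow(records))
  records[, c("row", RECORD_COLUMNS)]
}

#' Write records to CSV in the canonical column order
#' @param records a record data.frame.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records[, RECORD_COLUMNS], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
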