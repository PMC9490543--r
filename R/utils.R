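# internal helpers shared across modules

#' Normalize a source value for terminology lookup
#'
#' Case-folds, trims, and collapses internal whitespace.  This is the only
#' normalization applied before lookup; there is no fuzzy matching, so audits
#' stay deterministic and reviewable.
#'
#' @param x character vector of raw source values.
#' @return character vector of normalized values.
#' @export
#' @examples
#' normalize_value("  White   Non Hispanic ")
normalize_value <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Round a fraction to a printed percentage (half-up, one decimal)
#'
#' Multiplies by 100 and rounds half-up to one decimal place, the convention
#' used when reporting audit percentages (base \code{round()} rounds half to
#' even, which would not reproduce printed tables).
#'
#' @param frac numeric vector of fractions in \[0, 1\] (NA allowed).
#' @param digits decimal places of the percentage (default 1).
#' @return numeric vector of percentages.
#' @export
#' @examples
#' pct_round(217476 / 356778)  # 61.0
pct_round <- function(frac, digits = 1) {
  m <- 10^digits
  out <- floor(frac * 100 * m + 0.5 + 1e-9) / m
  out[is.na(frac)] <- NA_real_
  out
}

# fraction that reports NA (not 0) on an empty margin
safe_frac <- function(num, den) {
  ifelse(is.na(den) | den == 0, NA_real_, num / den)
}

# weighted sum by one or two grouping factors, returning named numeric
wt_sum <- function(w, by) {
  if (length(w) == 0L) return(stats::setNames(numeric(0), character(0)))
  s <- tapply(w, by, sum)
  s[is.na(s)] <- 0
  stats::setNames(as.numeric(s), names(s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_config <- function(...) stop(sprintf(...), call. = FALSE)
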