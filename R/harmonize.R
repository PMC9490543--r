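# Harmonization: resolve source values, roll up, reduce to one main concept
# per record, or audit the upstream (site/enclave) harmonization as delivered.

#' Harmonize demographic records
#'
#' For each record, resolves every race value through its code system (with
#' synonym fallback), rolls granular concepts up to their main category, and
#' reduces the value list to a single harmonized race concept: no values map
#' to the \code{MISSING_SENTINEL}, one distinct main concept maps to that
#' concept, two or more distinct mains map to the \code{MULTIPLE_RACE} flag,
#' and fully unresolvable values map to \code{NO_MATCHING_CONCEPT}.  A mix of
#' one resolvable main plus unresolvable noise reduces to the main (strict
#' mode reduces it to \code{NO_MATCHING_CONCEPT} instead).  Ethnicity is
#' reduced the same way from its single value, with granular Hispanic
#' subcategories rolling up to \code{HISPANIC}.
#'
#' In \code{"upstream"} mode the delivered \code{harmonized_race} /
#' \code{harmonized_ethnicity} columns are taken verbatim (falling back to
#' recomputation, with a logged notice, where they are absent), which is how
#' an audit of an enclave's own mapping is run.  \code{"recompute"} ignores
#' them; \code{"both"} keeps both results for disagreement analysis.
#'
#' @param registry an \code{re_registry}.
#' @param records a record data.frame (see \code{\link{read_records}}).
#' @param mode one of \code{"upstream"}, \code{"recompute"}, \code{"both"}.
#' @param delimiters multi-select delimiters (see
#'   \code{\link{parse_multiselect}}).
#' @param strict if TRUE, a resolvable main mixed with unresolvable noise
#'   reduces to \code{NO_MATCHING_CONCEPT}.
#' @return data.frame aligned with \code{records}: resolved concepts, the
#'   harmonized race/ethnicity mains under each provenance, and the
#'   token-level evidence used by conformance classification.  Notices are
#'   attached as attribute \code{harmonize_log}.
#' @export
harmonize_records <- function(registry, records,
                              mode = c("upstream", "recompute", "both"),
                              delimiters = DEFAULT_DELIMITERS, strict = FALSE) {
  stopifnot(inherits(registry, "re_registry"))
  mode <- match.arg(mode)
  records <- validate_records(records)
  n <- nrow(records)
  maps <- registry$maps

  toks <- parse_multiselect(records$race_value, delimiters)
  nt <- lengths(toks)
  idx <- rep.int(seq_len(n), nt)
  tok <- unlist(toks, use.names = FALSE)
  if (is.null(tok)) tok <- character(0)
  sys <- records$race_system[idx]
  bad_sys <- setdiff(unique(sys), registry$systems$system_id)
  if (length(bad_sys))
    abort_config("unknown race code system(s): %s", paste(bad_sys, collapse = ", "))

  cid <- unname(maps$entry[paste(sys, tok, sep = KEY_SEP)])
  syn <- unname(maps$syn_group[tok])
  fall <- is.na(cid) & !is.na(syn)
  cid[fall] <- unname(SYNONYM_TARGETS[syn[fall]])
  lev <- unname(maps$level[cid])
  axis <- unname(maps$axis[cid])
  main_tok <- rep(NA_character_, length(cid))
  is_race_concept <- !is.na(lev) & lev %in% c("MAIN", "GRANULAR") & axis == "RACE"
  main_tok[is_race_concept] <- rollup_to_main(registry, cid[is_race_concept])
  is_flag <- !is.na(lev) & lev == "FLAG"

  tok_missing <- (!is.na(syn) & syn %in% c("MISSING", "UNKNOWN")) |
    (!is.na(cid) & cid %in% MISSING_FLAGS)
  tok_refused <- (!is.na(syn) & syn == "REFUSED") | (!is.na(cid) & cid == "REFUSED")
  tok_other   <- (!is.na(syn) & syn == "OTHER")   | (!is.na(cid) & cid %in% OTHER_FLAGS)
  tok_multi   <- (!is.na(syn) & syn == "MULTIRACIAL") | (!is.na(cid) & cid == "MULTIPLE_RACE")
  tok_hisp    <- !is.na(cid) & cid == "HISPANIC"
  tok_gran    <- !is.na(lev) & lev == "GRANULAR" & axis == "RACE"

  agg <- function(x, f, default) {
    out <- rep(default, n)
    if (length(idx)) {
      s <- tapply(x, idx, f)
      out[as.integer(names(s))] <- unlist(s, use.names = FALSE)
    }
    out
  }
  all_missing_tok <- agg(tok_missing, all, FALSE)
  any_refused <- agg(tok_refused, any, FALSE)
  any_other   <- agg(tok_other, any, FALSE)
  any_multi   <- agg(tok_multi, any, FALSE)
  any_hisp    <- agg(tok_hisp, any, FALSE)
  any_gran_src <- agg(tok_gran, any, FALSE)
  any_unresolved <- agg(is.na(cid), any, FALSE)
  n_distinct_mains <- agg(main_tok, function(x) length(unique(x[!is.na(x)])), 0L)
  source_main <- agg(main_tok, function(x) {
    y <- x[!is.na(x)]
    if (length(y)) y[1] else NA_character_
  }, NA_character_)
  first_flag <- agg(ifelse(is_flag, cid, NA_character_), function(x) {
    y <- x[!is.na(x)]
    if (length(y)) y[1] else NA_character_
  }, NA_character_)
  cid_print <- cid
  cid_print[is.na(cid_print)] <- "NO_MATCH"
  race_concepts <- rep("", n)
  if (length(idx)) {
    s <- tapply(cid_print, idx, paste, collapse = ";")
    race_concepts[as.integer(names(s))] <- s
  }

  # reduction (recomputed race main)
  race_rec <- rep("NO_MATCHING_CONCEPT", n)
  race_rec[nt == 0L] <- "MISSING_SENTINEL"
  one <- n_distinct_mains == 1L
  race_rec[one] <- source_main[one]
  if (strict) race_rec[one & any_unresolved] <- "NO_MATCHING_CONCEPT"
  race_rec[n_distinct_mains >= 2L] <- "MULTIPLE_RACE"
  flag_only <- nt > 0L & n_distinct_mains == 0L & !is.na(first_flag)
  race_rec[flag_only] <- first_flag[flag_only]
  n_noise <- sum(one & any_unresolved & !strict)

  # ethnicity (recomputed)
  ev <- normalize_value(records$ethnicity_value)
  has_ev <- nzchar(ev)
  eth_rec <- rep("MISSING_SENTINEL", n)
  if (any(has_ev)) {
    esys <- records$ethnicity_system[has_ev]
    bad_esys <- setdiff(unique(esys), c("", registry$systems$system_id))
    if (length(bad_esys))
      abort_config("unknown ethnicity code system(s): %s", paste(bad_esys, collapse = ", "))
    ecid <- unname(maps$entry[paste(esys, ev[has_ev], sep = KEY_SEP)])
    esyn <- unname(maps$syn_group[ev[has_ev]])
    efall <- is.na(ecid) & !is.na(esyn)
    ecid[efall] <- unname(SYNONYM_TARGETS[esyn[efall]])
    elev <- unname(maps$level[ecid])
    eaxis <- unname(maps$axis[ecid])
    gr <- !is.na(elev) & elev == "GRANULAR" & eaxis == "ETHNICITY"
    ecid[gr] <- unname(maps$parent[ecid[gr]])
    # a race-axis concept in the ethnicity field is not interpretable ethnicity
    ecid[!is.na(elev) & elev != "FLAG" & eaxis == "RACE"] <- "NO_MATCHING_CONCEPT"
    ecid[is.na(ecid)] <- "NO_MATCHING_CONCEPT"
    eth_rec[has_ev] <- ecid
  }

  # upstream harmonization, verbatim where present
  resolve_upstream <- function(h) {
    h <- as.character(h)
    h[is.na(h)] <- ""
    known <- h %in% registry$concepts$concept_id
    disp <- unname(maps$by_display[normalize_value(h)])
    use_disp <- !known & nzchar(h) & !is.na(disp)
    h[use_disp] <- disp[use_disp]
    unknown <- nzchar(h) & !(h %in% registry$concepts$concept_id)
    h[unknown] <- "NO_MATCHING_CONCEPT"
    list(value = h, n_unknown = sum(unknown))
  }
  up_r <- resolve_upstream(records$harmonized_race)
  up_e <- resolve_upstream(records$harmonized_ethnicity)

  if (mode == "recompute") {
    race_main <- race_rec
    eth_main <- eth_rec
    prov_race <- rep("RECOMPUTED", n)
    prov_eth <- rep("RECOMPUTED", n)
  } else {
    has_ur <- nzchar(up_r$value)
    has_ue <- nzchar(up_e$value)
    race_main <- ifelse(has_ur, up_r$value, race_rec)
    eth_main <- ifelse(has_ue, up_e$value, eth_rec)
    prov_race <- ifelse(has_ur, "UPSTREAM", "RECOMPUTED")
    prov_eth <- ifelse(has_ue, "UPSTREAM", "RECOMPUTED")
  }
  race_main_level <- unname(maps$level[race_main])

  out <- data.frame(race_concepts = race_concepts,
                    race_main = race_main,
                    race_main_recomputed = race_rec,
                    ethnicity_main = eth_main,
                    ethnicity_main_recomputed = eth_rec,
                    provenance_race = prov_race,
                    provenance_ethnicity = prov_eth,
                    race_main_level = ifelse(is.na(race_main_level), "FLAG", race_main_level),
                    n_values = nt,
                    n_distinct_mains = n_distinct_mains,
                    source_main = source_main,
                    all_missing_tok = all_missing_tok,
                    any_refused_tok = any_refused,
                    any_other_tok = any_other,
                    any_multi_tok = any_multi,
                    any_hispanic_in_race = any_hisp,
                    any_granular_source = any_gran_src,
                    any_unresolved = any_unresolved,
                    stringsAsFactors = FALSE)
  attr(out, "harmonize_log") <- list(
    mode = mode,
    n_noise_reduced = n_noise,
    n_upstream_unknown = up_r$n_unknown + up_e$n_unknown,
    n_fallback_race = if (mode == "recompute") 0L else sum(!nzchar(up_r$value)),
    n_fallback_ethnicity = if (mode == "recompute") 0L else sum(!nzchar(up_e$value)))
  out
}

#' Tabulate original source encodings
#'
#' Enumerates, for one axis, every distinct (code system, normalized value)
#' pair present in the records, the main concept it maps to after resolution
#' and roll-up, how many distinct sites reported it, and the total patient
#' weight reported with it.  Grouping this table by the mapped concept gives
#' the "how many distinct ways was each category reported" counts.
#'
#' @param registry an \code{re_registry}.
#' @param records a record data.frame.
#' @param axis \code{"race"} or \code{"ethnicity"}.
#' @param delimiters multi-select delimiters (race axis only).
#' @return data.frame with columns \code{system_id}, \code{value},
#'   \code{mapped_concept}, \code{mapped_display}, \code{n_sites},
#'   \code{weight}, ordered by concept then descending weight.
#' @export
tabulate_source_encodings <- function(registry, records, axis = c("race", "ethnicity"),
                                      delimiters = DEFAULT_DELIMITERS) {
  axis <- match.arg(axis)
  records <- validate_records(records)
  n <- nrow(records)
  if (axis == "race") {
    toks <- parse_multiselect(records$race_value, delimiters)
    idx <- rep.int(seq_len(n), lengths(toks))
    tok <- unlist(toks, use.names = FALSE)
    sys <- records$race_system[idx]
  } else {
    tok <- normalize_value(records$ethnicity_value)
    idx <- which(nzchar(tok))
    tok <- tok[idx]
    sys <- records$ethnicity_system[idx]
  }
  if (length(tok) == 0L)
    return(data.frame(system_id = character(0), value = character(0),
                      mapped_concept = character(0), mapped_display = character(0),
                      n_sites = integer(0), weight = numeric(0)))
  # a patient reported with the same value twice in one multi-select counts once
  dup <- duplicated(data.frame(idx, sys, tok))
  idx <- idx[!dup]; sys <- sys[!dup]; tok <- tok[!dup]

  cid <- unname(registry$maps$entry[paste(sys, tok, sep = KEY_SEP)])
  syn <- unname(registry$maps$syn_group[tok])
  fall <- is.na(cid) & !is.na(syn)
  cid[fall] <- unname(SYNONYM_TARGETS[syn[fall]])
  lev <- unname(registry$maps$level[cid])
  roll <- !is.na(lev) & lev == "GRANULAR"
  cid[roll] <- unname(registry$maps$parent[cid[roll]])
  cid[is.na(cid)] <- "NO_MATCH"

  key <- paste(sys, tok, sep = KEY_SEP)
  w <- wt_sum(records$weight[idx], key)
  sites <- tapply(records$site_id[idx], key, function(s) length(unique(s)))
  first <- !duplicated(key)
  tab <- data.frame(system_id = sys[first], value = tok[first],
                    mapped_concept = cid[first], stringsAsFactors = FALSE)
  k <- paste(tab$system_id, tab$value, sep = KEY_SEP)
  tab$mapped_display <- concept_display(registry, tab$mapped_concept)
  tab$n_sites <- as.integer(sites[k])
  tab$weight <- as.numeric(w[k])
  tab <- tab[order(tab$mapped_concept, -tab$weight, tab$system_id, tab$value), ]
  rownames(tab) <- NULL
  tab
}
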