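# Terminology registry: concepts, per-dialect code systems, synonym groups.

RACE_MAINS <- c("AIAN", "ASIAN", "BLACK_AA", "NHPI", "WHITE")
ETH_MAINS  <- c("HISPANIC", "NOT_HISPANIC")
MISSING_FLAGS <- c("UNKNOWN", "NO_INFORMATION", "NULL_VALUE", "MISSING_SENTINEL")
OTHER_FLAGS   <- c("OTHER", "OTHER_RACE")
NONCONF_CATEGORIES <- c("MISSING", "OTHER", "REFUSED", "MULTIRACIAL",
                        "MISCLASSIFIED", "UNINTERPRETABLE", "MORE_GRANULAR")
# classification precedence: overlaps resolve toward the more specific
# data-collection phenomenon (a granular value that is also mismapped is
# MORE_GRANULAR, not MISCLASSIFIED)
CLASSIFY_PRECEDENCE <- c("MISSING", "REFUSED", "OTHER", "MULTIRACIAL",
                         "MORE_GRANULAR", "MISCLASSIFIED", "UNINTERPRETABLE")
DATA_MODELS <- c("OMOP", "OMOP_PEDSNET", "PCORNET", "ACT", "TRINETX", "LOCAL")

# group label -> flag concept reached through synonym fallback
SYNONYM_TARGETS <- c(REFUSED = "REFUSED", MULTIRACIAL = "MULTIPLE_RACE",
                     MISSING = "MISSING_SENTINEL", UNKNOWN = "UNKNOWN",
                     OTHER = "OTHER")

KEY_SEP <- "\x1f"

#' Path to the terminology files shipped with the package
#' @return directory containing \code{concepts.yaml}, \code{code_systems.yaml}
#'   and \code{synonyms.yaml}.
#' @export
default_terminology <- function() {
  system.file("extdata", "terminology", package = "raceaudit", mustWork = TRUE)
}

#' Load the terminology registry
#'
#' Reads the concept table, per-dialect code systems and synonym groups from
#' YAML files and validates referential integrity: every granular concept must
#' have a main-level parent on the same axis, every code-system entry must
#' target a registered concept, the main race/ethnicity sets must be exactly
#' the OMB minimum categories, and synonym groups must be pairwise disjoint.
#'
#' @param path directory containing \code{concepts.yaml},
#'   \code{code_systems.yaml} and \code{synonyms.yaml}; defaults to the files
#'   shipped with the package.
#' @return an object of class \code{re_registry}.
#' @export
load_registry <- function(path = default_terminology()) {
  files <- file.path(path, c("concepts.yaml", "code_systems.yaml", "synonyms.yaml"))
  for (f in files) {
    if (!file.exists(f)) abort_config("terminology file not found: %s", f)
  }
  parse_yaml <- function(f) {
    tryCatch(yaml::read_yaml(f),
             error = function(e) abort_config("parse error in %s: %s", f, conditionMessage(e)))
  }
  cy <- parse_yaml(files[1]); sy <- parse_yaml(files[2]); gy <- parse_yaml(files[3])

  if (is.null(cy$concepts)) abort_config("malformed %s: no 'concepts' table", files[1])
  empty_concepts <- data.frame(concept_id = character(0), display = character(0),
                               axis = character(0), level = character(0),
                               parent = character(0), hl7_code = character(0),
                               stringsAsFactors = FALSE)
  concepts <- do.call(rbind, lapply(cy$concepts, function(cc) {
    data.frame(concept_id = as.character(cc$concept_id %||% NA),
               display = as.character(cc$display %||% ""),
               axis = as.character(cc$axis %||% ""),
               level = as.character(cc$level %||% ""),
               parent = as.character(cc$parent %||% ""),
               hl7_code = as.character(cc$hl7_code %||% ""),
               stringsAsFactors = FALSE)
  })) %||% empty_concepts

  systems <- data.frame(system_id = character(0), data_model = character(0),
                        stringsAsFactors = FALSE)
  entries <- list()
  for (s in sy$systems %||% list()) {
    sid <- as.character(s$system_id)
    systems <- rbind(systems, data.frame(system_id = sid,
                                         data_model = as.character(s$data_model %||% "LOCAL"),
                                         stringsAsFactors = FALSE))
    vals <- names(s$entries %||% list())
    if (length(vals)) {
      entries[[sid]] <- data.frame(system_id = sid,
                                   value = normalize_value(vals),
                                   concept_id = as.character(unlist(s$entries, use.names = FALSE)),
                                   stringsAsFactors = FALSE)
    }
  }
  entries <- if (length(entries)) do.call(rbind, entries) else
    data.frame(system_id = character(0), value = character(0),
               concept_id = character(0), stringsAsFactors = FALSE)
  rownames(entries) <- NULL

  synonyms <- do.call(rbind, lapply(names(gy$groups %||% list()), function(g) {
    data.frame(group = g, value = normalize_value(unlist(gy$groups[[g]])),
               stringsAsFactors = FALSE)
  })) %||% data.frame(group = character(0), value = character(0), stringsAsFactors = FALSE)

  reg <- structure(list(concepts = concepts, systems = systems,
                        entries = entries, synonyms = synonyms,
                        version = as.character(cy$version %||% "0")),
                   class = "re_registry")
  validate_registry(reg)
  reg$maps <- build_registry_maps(reg)
  reg
}

validate_registry <- function(reg) {
  co <- reg$concepts
  problems <- character(0)
  if (anyDuplicated(co$concept_id))
    problems <- c(problems, paste("duplicate concept ids:",
                                  paste(unique(co$concept_id[duplicated(co$concept_id)]), collapse = ", ")))
  mains_race <- sort(co$concept_id[co$level == "MAIN" & co$axis == "RACE"])
  if (!identical(mains_race, sort(RACE_MAINS)))
    problems <- c(problems, "MAIN race concepts must be exactly the 5 OMB minimum categories")
  mains_eth <- sort(co$concept_id[co$level == "MAIN" & co$axis == "ETHNICITY"])
  if (!identical(mains_eth, sort(ETH_MAINS)))
    problems <- c(problems, "MAIN ethnicity concepts must be exactly the 2 standard categories")
  gran <- co[co$level == "GRANULAR", ]
  for (i in seq_len(nrow(gran))) {
    p <- co[co$concept_id == gran$parent[i], ]
    if (nrow(p) == 0L)
      problems <- c(problems, sprintf("granular concept %s has missing parent %s",
                                      gran$concept_id[i], gran$parent[i]))
    else if (p$level != "MAIN" || p$axis != gran$axis[i])
      problems <- c(problems, sprintf("granular concept %s: parent %s is not a MAIN concept on the same axis",
                                      gran$concept_id[i], gran$parent[i]))
  }
  if (any(co$parent[co$level == "FLAG"] != ""))
    problems <- c(problems, "FLAG concepts must have no parent")
  dangling <- setdiff(reg$entries$concept_id, co$concept_id)
  if (length(dangling))
    problems <- c(problems, paste("code-system entries target unregistered concepts:",
                                  paste(unique(dangling), collapse = ", ")))
  keys <- paste(reg$entries$system_id, reg$entries$value, sep = KEY_SEP)
  if (anyDuplicated(keys))
    problems <- c(problems, "duplicate lookup keys after normalization")
  if (anyDuplicated(reg$synonyms$value))
    problems <- c(problems, paste("synonym groups are not disjoint:",
                                  paste(unique(reg$synonyms$value[duplicated(reg$synonyms$value)]), collapse = ", ")))
  bad_groups <- setdiff(unique(reg$synonyms$group), names(SYNONYM_TARGETS))
  if (length(bad_groups))
    problems <- c(problems, paste("unknown synonym group(s):", paste(bad_groups, collapse = ", ")))
  if (length(problems))
    abort_config("terminology integrity error:\n  - %s", paste(problems, collapse = "\n  - "))
  invisible(TRUE)
}

build_registry_maps <- function(reg) {
  co <- reg$concepts
  list(entry = stats::setNames(reg$entries$concept_id,
                               paste(reg$entries$system_id, reg$entries$value, sep = KEY_SEP)),
       syn_group = stats::setNames(reg$synonyms$group, reg$synonyms$value),
       level = stats::setNames(co$level, co$concept_id),
       axis = stats::setNames(co$axis, co$concept_id),
       parent = stats::setNames(co$parent, co$concept_id),
       display = stats::setNames(co$display, co$concept_id),
       by_display = stats::setNames(co$concept_id, normalize_value(co$display)))
}

#' Write a registry back to terminology files
#'
#' Serializes a registry to the three YAML files understood by
#' \code{\link{load_registry}}; reloading the written files yields an
#' identical registry (round-trip property).
#'
#' @param registry an \code{re_registry}.
#' @param path output directory (created if needed).
#' @return \code{path}, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "re_registry"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  co <- registry$concepts
  clist <- lapply(seq_len(nrow(co)), function(i) {
    x <- list(concept_id = co$concept_id[i], display = co$display[i],
              axis = co$axis[i], level = co$level[i])
    if (co$parent[i] != "") x$parent <- co$parent[i]
    if (co$hl7_code[i] != "") x$hl7_code <- co$hl7_code[i]
    x
  })
  yaml::write_yaml(list(version = registry$version, concepts = clist),
                   file.path(path, "concepts.yaml"))
  slist <- lapply(seq_len(nrow(registry$systems)), function(i) {
    sid <- registry$systems$system_id[i]
    e <- registry$entries[registry$entries$system_id == sid, ]
    list(system_id = sid, data_model = registry$systems$data_model[i],
         entries = as.list(stats::setNames(e$concept_id, e$value)))
  })
  yaml::write_yaml(list(version = registry$version, systems = slist),
                   file.path(path, "code_systems.yaml"))
  groups <- split(registry$synonyms$value, registry$synonyms$group)
  yaml::write_yaml(list(version = registry$version, groups = lapply(groups, as.list)),
                   file.path(path, "synonyms.yaml"))
  invisible(path)
}

#' @export
print.re_registry <- function(x, ...) {
  co <- x$concepts
  cat("<re_registry> version", x$version, "\n")
  cat(sprintf("  %d concepts (%d MAIN race, %d MAIN ethnicity, %d granular, %d flags)\n",
              nrow(co), sum(co$level == "MAIN" & co$axis == "RACE"),
              sum(co$level == "MAIN" & co$axis == "ETHNICITY"),
              sum(co$level == "GRANULAR"), sum(co$level == "FLAG")))
  cat(sprintf("  %d code systems, %d entries, %d synonym values\n",
              nrow(x$systems), nrow(x$entries), nrow(x$synonyms)))
  invisible(x)
}

#' Resolve a raw source value to a concept
#'
#' Normalizes \code{raw_value}, then looks it up in the code system's entry
#' table; on a miss, falls back to the canonical synonym groups (which map to
#' flag concepts such as \code{REFUSED} or \code{MISSING_SENTINEL}).  Unknown
#' strings return \code{NO_MATCH}, never an error.
#'
#' @param registry an \code{re_registry}.
#' @param system_id a registered code system.
#' @param raw_value character vector of raw values (may be empty strings).
#' @return data.frame with columns \code{concept_id} (\code{"NO_MATCH"} when
#'   unresolvable) and \code{matched_via} (\code{CODE}, \code{SYNONYM} or
#'   \code{NONE}).
#' @export
#' @examples
#' reg <- load_registry()
#' resolve_code(reg, "PCORNET_RACE", c("05", " 05 ", "@"))
resolve_code <- function(registry, system_id, raw_value) {
  stopifnot(inherits(registry, "re_registry"))
  if (!system_id %in% registry$systems$system_id)
    abort_config("unknown code system: %s", system_id)
  v <- normalize_value(raw_value)
  cid <- unname(registry$maps$entry[paste(system_id, v, sep = KEY_SEP)])
  via <- ifelse(is.na(cid), "NONE", "CODE")
  miss <- is.na(cid)
  if (any(miss)) {
    grp <- unname(registry$maps$syn_group[v[miss]])
    hit <- !is.na(grp)
    cid[miss][hit] <- unname(SYNONYM_TARGETS[grp[hit]])
    via[miss][hit] <- "SYNONYM"
  }
  cid[is.na(cid)] <- "NO_MATCH"
  data.frame(concept_id = cid, matched_via = via, stringsAsFactors = FALSE)
}

#' Roll a concept up to its main category
#'
#' Granular concepts map to their MAIN parent; MAIN and FLAG concepts map to
#' themselves (flags have no main ancestor).  Idempotent.
#'
#' @param registry an \code{re_registry}.
#' @param concept_id character vector of registered concept ids.
#' @return character vector of concept ids.
#' @export
#' @examples
#' reg <- load_registry()
#' rollup_to_main(reg, c("ASIAN_INDIAN", "JEWISH", "WHITE"))
rollup_to_main <- function(registry, concept_id) {
  stopifnot(inherits(registry, "re_registry"))
  lev <- registry$maps$level[concept_id]
  if (anyNA(lev))
    abort_config("unknown concept id(s): %s",
                 paste(unique(concept_id[is.na(lev)]), collapse = ", "))
  out <- concept_id
  g <- !is.na(lev) & lev == "GRANULAR"
  out[g] <- unname(registry$maps$parent[concept_id[g]])
  unname(out)
}

#' Human-readable display label for concept ids
#' @param registry an \code{re_registry}.
#' @param concept_id character vector of concept ids (unknown ids pass through).
#' @return character vector of display labels.
#' @export
concept_display <- function(registry, concept_id) {
  d <- registry$maps$display[concept_id]
  ifelse(is.na(d), concept_id, unname(d))
}
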