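# Species/threat data model: reclassification of Red List threat codes
# into six broad categories and the major-threat filters on scope,
# severity and timing.

#' The six broad threat categories
#'
#' The broad categories follow the drivers recognised by the Convention on
#' Biological Diversity: habitat loss (including degradation),
#' overexploitation for international trade, pollution, invasive species,
#' climate change, and a residual "other" class (unknown threats, natural
#' causes such as volcanic eruptions, and overexploitation records that do
#' not involve intentional international trade).
#'
#' @return character vector of the six category labels.
#' @export
cbd_categories <- function() {
  c("habitat_loss", "overexploitation_international_trade", "pollution",
    "invasive_species", "climate_change", "other")
}

# vocabulary for threat record fields
threat_scope_levels <- function() c("minority_lt50", "majority_gt50", "whole", "unknown")
threat_severity_levels <- function() {
  c("negligible", "slow_significant", "rapid", "very_rapid", "fluctuating", "unknown")
}
threat_timing_levels <- function() {
  c("past", "past_unlikely_to_return", "ongoing", "future", "unknown")
}
redlist_categories <- function() c("LC", "NT", "VU", "EN", "CR", "EW", "EX")

#' Is a Red List category "threatened"?
#'
#' @param category character vector of Red List categories.
#' @return logical: `TRUE` for VU, EN and CR.
#' @export
is_threatened <- function(category) category %in% c("VU", "EN", "CR")

#' Default threat-code reclassification table
#'
#' The mapping from Red List threat classification codes (levels 1 and 2)
#' to the six broad categories ships as an editable CSV
#' (`cbd_threat_mapping.csv` in the package's `extdata`). Users may supply
#' their own table to [reclassify_threat()]; the shipped default is a
#' reconstruction covering all level-1/level-2 codes, not a canonical
#' standard. Note the mapping carries the *pre-restriction* category for
#' overexploitation codes: the international-trade restriction and the
#' ecosystem-stress restriction for habitat loss are applied downstream by
#' [major_cbd_threats()].
#'
#' @return tibble with columns `code`, `cbd_category`, `notes`.
#' @export
cbd_default_mapping <- function() {
  path <- system.file("extdata", "cbd_threat_mapping.csv", package = "consgap")
  read_threat_mapping(path)
}

#' @rdname cbd_default_mapping
#' @param path path to a mapping CSV with columns `code`, `cbd_category`
#'   and optionally `notes`.
#' @export
read_threat_mapping <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  req <- c("code", "cbd_category")
  if (!all(req %in% names(m)))
    stop("threat mapping must have columns 'code' and 'cbd_category'", call. = FALSE)
  valid <- c(cbd_categories(), "overexploitation")
  bad <- setdiff(unique(m$cbd_category), valid)
  if (length(bad) > 0)
    stop("unknown cbd_category value(s) in mapping: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(m$code))
    stop("threat mapping has duplicated codes: ",
         paste(unique(m$code[duplicated(m$code)]), collapse = ", "), call. = FALSE)
  m$code <- as.character(m$code)
  m
}

#' Reclassify a Red List threat code into a broad category
#'
#' Total over the mapping's domain; any code absent from the mapping is an
#' explicit error naming the code. The raw mapping category
#' `"overexploitation"` is returned as-is here; whether a record counts as
#' `overexploitation_international_trade` or falls to `other` depends on
#' its intentional-use/international-trade flag and is decided by
#' [major_cbd_threats()].
#'
#' @param code character vector of threat codes (e.g. `"5.1"`).
#' @param mapping a mapping table from [cbd_default_mapping()] or
#'   [read_threat_mapping()].
#' @return character vector of broad categories, same length as `code`.
#' @export
reclassify_threat <- function(code, mapping = cbd_default_mapping()) {
  code <- as.character(code)
  idx <- match(code, mapping$code)
  if (anyNA(idx)) {
    missing <- unique(code[is.na(idx)])
    stop("unmapped threat code(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  mapping$cbd_category[idx]
}

#' Major-threat test on scope, severity and timing
#'
#' A threat is "major" when it affects more than 50% of the global
#' population (scope majority/whole), has caused slow-significant, rapid
#' or very rapid declines, and occurred in the past or is ongoing (never a
#' predicted future threat). Records with unknown scope or severity can be
#' included optionally, because many assessments leave these fields
#' unknown; unknown *timing* never qualifies. "Causing/could cause
#' fluctuations" severity does not qualify.
#'
#' @param scope,severity,timing character vectors (equal length) with the
#'   Red List-style values: scope in `minority_lt50`, `majority_gt50`,
#'   `whole`, `unknown`; severity in `negligible`, `slow_significant`,
#'   `rapid`, `very_rapid`, `fluctuating`, `unknown`; timing in `past`,
#'   `past_unlikely_to_return`, `ongoing`, `future`, `unknown`.
#' @param include_unknown treat unknown scope/severity as qualifying?
#' @return logical vector.
#' @export
is_major_threat <- function(scope, severity, timing, include_unknown = TRUE) {
  check_enum(scope, threat_scope_levels(), "scope")
  check_enum(severity, threat_severity_levels(), "severity")
  check_enum(timing, threat_timing_levels(), "timing")
  scope_ok <- scope %in% c("majority_gt50", "whole") |
    (include_unknown & scope == "unknown")
  sev_ok <- severity %in% c("slow_significant", "rapid", "very_rapid") |
    (include_unknown & severity == "unknown")
  time_ok <- timing %in% c("past", "past_unlikely_to_return", "ongoing")
  scope_ok & sev_ok & time_ok
}

check_enum <- function(x, levels, what) {
  bad <- setdiff(unique(x[!is.na(x)]), levels)
  if (length(bad) > 0)
    stop("invalid ", what, " value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyNA(x))
    stop(what, " contains missing values; use the explicit value 'unknown'",
         call. = FALSE)
  invisible(x)
}

# ecosystem/community stresses: conversion (1.1), degradation (1.2),
# indirect effects such as fragmentation (1.3) — any code under "1".
has_ecosystem_stress <- function(stresses) {
  vapply(split_codes(stresses), function(s) any(grepl("^1($|\\.)", s)), logical(1))
}

split_codes <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) character(0)
    else trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

#' Major broad-category threats per species
#'
#' Applies the major-threat filter to every threat record, reclassifies the
#' survivors, and applies two restrictions: a record contributes
#' `habitat_loss` only if its stresses include an ecosystem/community
#' stress (codes under "1" of the stress scheme — conversion, degradation,
#' indirect effects), because threats like recreational activities can
#' instead stress the species directly while leaving habitat intact; and an
#' overexploitation record contributes
#' `overexploitation_international_trade` only when flagged as intentional
#' use of an internationally traded species, falling to `other` otherwise
#' (e.g. local subsistence hunting).
#'
#' @param threats threat table: one row per species-threat pair with
#'   columns `taxon_id`, `code`, `scope`, `severity`, `timing`, `stresses`
#'   (semicolon-separated stress codes, may be empty) and
#'   `intentional_trade` (logical).
#' @param mapping reclassification table (see [cbd_default_mapping()]).
#' @param include_unknown passed to [is_major_threat()].
#' @return tibble with `taxon_id` and one logical column per broad
#'   category; one row per distinct `taxon_id` in `threats`.
#' @export
major_cbd_threats <- function(threats, mapping = cbd_default_mapping(),
                              include_unknown = TRUE) {
  cats <- cbd_categories()
  ids <- unique(threats$taxon_id)
  out <- tibble::tibble(taxon_id = ids)
  for (ct in cats) out[[ct]] <- FALSE
  if (nrow(threats) == 0) return(out)
  stopifnot(all(c("taxon_id", "code", "scope", "severity", "timing",
                  "stresses", "intentional_trade") %in% names(threats)))
  major <- is_major_threat(threats$scope, threats$severity, threats$timing,
                           include_unknown = include_unknown)
  raw_cat <- reclassify_threat(threats$code, mapping)
  eco <- has_ecosystem_stress(threats$stresses)
  trade <- as.logical(threats$intentional_trade)
  cat <- raw_cat
  cat[raw_cat == "overexploitation" & trade] <- "overexploitation_international_trade"
  cat[raw_cat == "overexploitation" & !trade] <- "other"
  # habitat loss requires an ecosystem-level stress; otherwise the record
  # contributes nothing (it is dropped, not reassigned)
  drop <- cat == "habitat_loss" & !eco
  keep <- major & !drop
  if (any(keep)) {
    hit <- unique(data.frame(taxon_id = threats$taxon_id[keep], cat = cat[keep]))
    for (k in seq_len(nrow(hit))) {
      i <- match(hit$taxon_id[k], out$taxon_id)
      out[[hit$cat[k]]][i] <- TRUE
    }
  }
  out
}
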