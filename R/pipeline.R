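# Pipeline driver: chains classify -> protect -> interventions ->
# summarize (+ status changes when supplied) over a world directory,
# with validation up front and a provenance log.

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. The toggles reproduce the
#' study's sensitivity analyses: `include_unknown` admits threats with
#' unknown scope/severity into the major-threat set;
#' `exclude_possibly_extinct` drops Possibly Extinct CR species;
#' `mode` switches the habitat criterion between meaningful representation
#' (strict) and meaningful-or-any-PA-occurrence (relaxed).
#'
#' @param input_dir directory holding the input bundle (see
#'   [write_world()] for the layout).
#' @param out_dir output directory.
#' @param mode `"strict"` or `"relaxed"`.
#' @param include_unknown include unknown scope/severity threats?
#' @param exclude_possibly_extinct drop Possibly Extinct species?
#' @param reference_year reference year for the occurrence-point fallback;
#'   default: the `reference_year` recorded in the bundle's `world.yaml`.
#' @param status_changes_path optional status-change CSV.
#' @param seed integer seed recorded in provenance (the pipeline itself is
#'   deterministic).
#' @return validated config list of class `cg_pipeline_config`.
#' @export
pipeline_config <- function(input_dir, out_dir, mode = c("strict", "relaxed"),
                            include_unknown = TRUE,
                            exclude_possibly_extinct = FALSE,
                            reference_year = NULL,
                            status_changes_path = NULL, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(is.logical(include_unknown), is.logical(exclude_possibly_extinct))
  cfg <- list(input_dir = input_dir, out_dir = out_dir, mode = mode,
              include_unknown = include_unknown,
              exclude_possibly_extinct = exclude_possibly_extinct,
              reference_year = reference_year,
              status_changes_path = status_changes_path, seed = seed)
  class(cfg) <- "cg_pipeline_config"
  cfg
}

#' Run the full conservation-gap pipeline
#'
#' Validates all inputs before any computation, then runs the stages in
#' order: major-threat classification, protection scoring, intervention
#' status, matched-intervention assessment, country summaries, and (when a
#' status-change table is supplied) genuine-change filtering and
#' cross-tabulation. All outputs are written to `config$out_dir` with
#' provenance headers; a `provenance_log.csv` records row counts in and
#' out of every stage so filter attrition is auditable. Deterministic
#' given config and inputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages?
#' @return (invisibly) list with `species`, `major`, `protection`,
#'   `statuses`, `matched`, `country_summary`, `country_summary_endemic`,
#'   and, when status changes were supplied, `status_changes` and
#'   `crosstabs`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "cg_pipeline_config"))
  say <- function(...) if (!quiet) message(...)

  # validate every referenced input before any computation
  needed <- c("grid.csv", "dem.csv", "species.csv", "threats.csv",
              "evidence.csv", "ranges.csv", "pas.csv", "islands.csv",
              "eradications.csv", "listings.csv", "taxonomy.csv",
              "points.csv", "world.yaml")
  missing <- needed[!file.exists(file.path(config$input_dir, needed))]
  if (length(missing) > 0)
    stop("pipeline input validation failed; missing file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!is.null(config$status_changes_path) &&
      !file.exists(config$status_changes_path))
    stop("pipeline input validation failed; missing file(s): ",
         config$status_changes_path, call. = FALSE)

  world <- read_world(config$input_dir)
  ref_year <- if (!is.null(config$reference_year)) config$reference_year
    else world$meta$reference_year
  prov <- list(config_hash = config_hash(unclass(config)), seed = config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_rows <- list()
  log_stage <- function(stage, n_in, n_out) {
    say(sprintf("[%s] %d -> %d", stage, n_in, n_out))
    log_rows[[length(log_rows) + 1]] <<- tibble::tibble(
      stage = stage, rows_in = n_in, rows_out = n_out)
  }

  # scope filter: threatened, terrestrial(-freshwater), optional PE filter
  sp <- world$tables$species
  n0 <- nrow(sp)
  sp <- sp[is_threatened(sp$redlist_category) &
             sp$system %in% c("terrestrial", "terrestrial_freshwater"), ,
           drop = FALSE]
  if (config$exclude_possibly_extinct)
    sp <- sp[!sp$possibly_extinct, , drop = FALSE]
  log_stage("scope_filter", n0, nrow(sp))

  # classify
  thr <- world$tables$threats
  thr <- thr[thr$taxon_id %in% sp$taxon_id, , drop = FALSE]
  major <- major_cbd_threats(thr, include_unknown = config$include_unknown)
  # species with no threat records still get a (all-FALSE) row
  major <- dplyr::left_join(tibble::tibble(taxon_id = sp$taxon_id), major,
                            by = "taxon_id")
  for (ct in cbd_categories())
    major[[ct]][is.na(major[[ct]])] <- FALSE
  log_stage("classify", nrow(thr), nrow(major))

  # protect
  protection <- protection_table(sp, world$tables$ranges, world$stack,
                                 world$tables$pas, world$tables$points,
                                 reference_year = ref_year)
  log_stage("protect", nrow(sp), nrow(protection))

  # interventions
  statuses <- intervention_status_table(
    sp, world$tables$evidence, protection, world$tables$ranges,
    islands = world$tables$islands, listings = world$tables$listings,
    taxonomy = world$tables$taxonomy,
    eradications = world$tables$eradications, mode = config$mode)
  matched <- matched_intervention_status(major, statuses, mode = config$mode)
  log_stage("interventions", nrow(sp), nrow(statuses))

  # summaries
  country_summary <- summarize_by_country(sp, !statuses$any_documented,
                                          endemics_only = FALSE,
                                          by_class = TRUE)
  country_summary_endemic <- summarize_by_country(sp,
                                                  !statuses$any_documented,
                                                  endemics_only = TRUE,
                                                  by_class = TRUE)
  log_stage("summarize", nrow(sp), nrow(country_summary))

  out <- list(species = sp, major = major, protection = protection,
              statuses = statuses, matched = matched,
              country_summary = country_summary,
              country_summary_endemic = country_summary_endemic)

  if (!is.null(config$status_changes_path)) {
    changes <- read_status_changes(config$status_changes_path)
    filtered <- filter_genuine(changes)
    log_stage("status_change_filter", nrow(changes), nrow(filtered))
    out$status_changes <- filtered
    out$crosstabs <- crosstab_status_changes(filtered, statuses, matched)
  }

  write_csv_prov(major, file.path(config$out_dir, "major_threats.csv"), prov)
  write_csv_prov(protection, file.path(config$out_dir, "protection.csv"), prov)
  write_csv_prov(statuses, file.path(config$out_dir, "intervention_status.csv"),
                 prov)
  write_csv_prov(matched, file.path(config$out_dir, "matched_interventions.csv"),
                 prov)
  write_csv_prov(country_summary,
                 file.path(config$out_dir, "country_summary.csv"), prov)
  write_csv_prov(country_summary_endemic,
                 file.path(config$out_dir, "country_summary_endemic.csv"), prov)
  if (!is.null(out$status_changes)) {
    write_csv_prov(out$status_changes,
                   file.path(config$out_dir, "status_changes_genuine.csv"),
                   prov)
    write_csv_prov(out$crosstabs$any_intervention,
                   file.path(config$out_dir, "crosstab_any_intervention.csv"),
                   prov)
    write_csv_prov(out$crosstabs$single_threat,
                   file.path(config$out_dir, "crosstab_single_threat.csv"),
                   prov)
  }
  write_csv_prov(dplyr::bind_rows(log_rows),
                 file.path(config$out_dir, "provenance_log.csv"), prov)
  invisible(out)
}
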