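# Readers/writers for all file schemas. CSV is the canonical tabular
# interchange; rasters are plain-text matrix CSVs plus a grid descriptor;
# geometries are rectangle-table CSVs. Every output carries a provenance
# header comment (config hash, seed), and all readers skip '#' comments,
# so outputs round-trip through the same readers.

csv_schemas <- list(
  species = list(
    required = c("taxon_id", "scientific_name", "taxon_class", "family",
                 "redlist_category", "possibly_extinct", "system",
                 "habitat_codes", "elevation_min_m", "elevation_max_m",
                 "countries", "endemic_country",
                 "evolutionary_distinctiveness", "named_invasives"),
    enums = list(redlist_category = c("LC", "NT", "VU", "EN", "CR", "EW", "EX"),
                 system = c("terrestrial", "terrestrial_freshwater", "other"))),
  threats = list(
    required = c("taxon_id", "code", "scope", "severity", "timing",
                 "stresses", "intentional_trade"),
    enums = list(scope = c("minority_lt50", "majority_gt50", "whole", "unknown"),
                 severity = c("negligible", "slow_significant", "rapid",
                              "very_rapid", "fluctuating", "unknown"),
                 timing = c("past", "past_unlikely_to_return", "ongoing",
                            "future", "unknown"))),
  evidence = list(
    required = c("taxon_id",
                 paste0(rep(c("pa_occurrence", "trade_control",
                              "invasive_control", "reintroduction",
                              "legislation", "education"), each = 2),
                        c("_tabular", "_text"))),
    enums = list()),
  listings = list(
    required = c("group", "instrument", "instrument_detail"),
    enums = list(instrument = c("CITES_appendix", "CMS", "EU_annex",
                                "named_agreement"))),
  eradications = list(
    required = c("island_id", "invasive_species_name", "outcome", "year"),
    enums = list(outcome = c("successful", "failed", "in_progress"))),
  status_changes = list(
    required = c("taxon_id", "year", "from_category", "to_category", "reason"),
    enums = list(reason = c("genuine", "nongenuine"),
                 from_category = c("LC", "NT", "VU", "EN", "CR", "EW", "EX"),
                 to_category = c("LC", "NT", "VU", "EN", "CR", "EW", "EX"))),
  rects = list(required = c("xmin", "ymin", "xmax", "ymax"), enums = list()),
  points = list(required = c("taxon_id", "x", "y", "year"), enums = list()),
  taxonomy = list(required = c("taxon_id"), enums = list()))

validate_table <- function(df, schema_name) {
  sch <- csv_schemas[[schema_name]]
  problems <- character(0)
  missing <- setdiff(sch$required, names(df))
  if (length(missing) > 0)
    problems <- c(problems, paste0("missing column(s): ",
                                   paste(missing, collapse = ", ")))
  if (length(missing) == 0) {
    for (col in names(sch$enums)) {
      bad <- which(!(df[[col]] %in% sch$enums[[col]]) & !is.na(df[[col]]))
      if (length(bad) > 0)
        problems <- c(problems,
                      paste0("invalid ", col, " value '",
                             df[[col]][bad[1]], "' in row(s): ",
                             paste(head(bad, 10), collapse = ", ")))
    }
  }
  if (length(problems) > 0)
    stop("schema '", schema_name, "': ",
         paste(problems, collapse = "; "), call. = FALSE)
  df
}

read_validated <- function(path, schema_name) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  validate_table(df, schema_name)
}

#' Read pipeline input tables
#'
#' Schema-validated CSV readers for every tabular input. Columns are
#' documented in the schema list shipped with the package; unknown enum
#' values are rejected with the offending row numbers, and lines starting
#' with `#` (provenance headers) are ignored, so the package's own outputs
#' round-trip.
#'
#' @param path path to a CSV file.
#' @return a validated tibble.
#' @name readers
NULL

#' @rdname readers
#' @export
read_species_table <- function(path) {
  df <- read_validated(path, "species")
  for (col in c("habitat_codes", "countries", "endemic_country",
                "named_invasives"))
    df[[col]] <- as.character(df[[col]])
  df
}

#' @rdname readers
#' @export
read_threats <- function(path) {
  df <- read_validated(path, "threats")
  df$code <- as.character(df$code)
  df$stresses <- as.character(df$stresses)
  df
}

#' @rdname readers
#' @export
read_evidence <- function(path) read_validated(path, "evidence")

#' @rdname readers
#' @export
read_listings <- function(path) read_validated(path, "listings")

#' @rdname readers
#' @export
read_eradications <- function(path) read_validated(path, "eradications")

#' @rdname readers
#' @export
read_status_changes <- function(path) read_validated(path, "status_changes")

#' @rdname readers
#' @export
read_rects_table <- function(path) read_validated(path, "rects")

#' @rdname readers
#' @export
read_points <- function(path) read_validated(path, "points")

#' @rdname readers
#' @export
read_taxonomy <- function(path) read_validated(path, "taxonomy")

#' Write a table with a provenance header
#'
#' Writes CSV prefixed with `#` comment lines recording the package
#' version, the config hash and seed, so every output is traceable to the
#' run that produced it and identical configs reproduce identical files.
#'
#' @param df data frame.
#' @param path output path.
#' @param provenance named list (e.g. `config_hash`, `seed`); may be `NULL`.
#' @return `path`, invisibly.
#' @export
write_csv_prov <- function(df, path, provenance = NULL) {
  lines <- c(paste0("# consgap ",
                    as.character(utils::packageVersion("consgap"))))
  for (nm in names(provenance))
    lines <- c(lines, paste0("# ", nm, ": ", provenance[[nm]]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Stable hash of a configuration object
#'
#' MD5 of the deparsed object, used in provenance headers.
#'
#' @param x any R object.
#' @return character scalar.
#' @export
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(x), tf)
  unname(tools::md5sum(tf))
}

#' Read and write grid-aligned rasters
#'
#' Rasters are stored as plain-text matrix CSVs (one row per grid row,
#' cells left-to-right along x) next to a `grid.csv` descriptor holding
#' `nx`, `ny`, `cell_km`, `origin_x`, `origin_y`.
#'
#' @param m matrix (`nx` by `ny`).
#' @param path file path.
#' @return `read_raster_csv()` returns a matrix; `read_grid()` a
#'   [cg_grid()].
#' @name raster_io
NULL

#' @rdname raster_io
#' @export
write_raster_csv <- function(m, path) {
  utils::write.table(t(m), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname raster_io
#' @export
read_raster_csv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  t(m)
}

#' @rdname raster_io
#' @param grid a [cg_grid()].
#' @export
write_grid <- function(grid, path) {
  df <- data.frame(nx = grid$nx, ny = grid$ny, cell_km = grid$cell_km,
                   origin_x = grid$origin[1], origin_y = grid$origin[2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname raster_io
#' @export
read_grid <- function(path) {
  df <- utils::read.csv(path)
  cg_grid(df$nx, df$ny, df$cell_km, c(df$origin_x, df$origin_y))
}

#' Write a generated world to a directory
#'
#' Serializes every table, the habitat layers (one CSV per class, named
#' `habitat_<code>.csv`), the DEM, the grid descriptor and the
#' ground-truth table, in the schemas the pipeline readers expect.
#'
#' @param world result of [generate_world()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(config_hash = config_hash(world$config), seed = world$seed)
  tb <- world$tables
  for (nm in names(tb))
    write_csv_prov(tb[[nm]], file.path(dir, paste0(nm, ".csv")), prov)
  write_csv_prov(world$ground_truth, file.path(dir, "ground_truth.csv"), prov)
  write_grid(world$grid, file.path(dir, "grid.csv"))
  write_raster_csv(world$stack$dem, file.path(dir, "dem.csv"))
  for (code in names(world$stack$layers))
    write_raster_csv(world$stack$layers[[code]],
                     file.path(dir, paste0("habitat_", code, ".csv")))
  yaml::write_yaml(list(reference_year = world$config$reference_year,
                        seed = world$seed,
                        habitat_classes = names(world$stack$layers)),
                   file.path(dir, "world.yaml"))
  invisible(dir)
}

#' Load a world directory into a stack + tables
#'
#' Inverse of [write_world()] (the ground-truth table is read only if
#' present).
#'
#' @param dir directory written by [write_world()].
#' @return list with `grid`, `stack`, `tables`, `meta` and optionally
#'   `ground_truth`.
#' @export
read_world <- function(dir) {
  grid <- read_grid(file.path(dir, "grid.csv"))
  dem <- read_raster_csv(file.path(dir, "dem.csv"))
  hab_files <- list.files(dir, pattern = "^habitat_.*\\.csv$", full.names = TRUE)
  layers <- list()
  for (f in hab_files) {
    code <- sub("^habitat_(.*)\\.csv$", "\\1", basename(f))
    layers[[code]] <- read_raster_csv(f)
  }
  tables <- list(
    species = read_species_table(file.path(dir, "species.csv")),
    threats = read_threats(file.path(dir, "threats.csv")),
    evidence = read_evidence(file.path(dir, "evidence.csv")),
    ranges = read_rects_table(file.path(dir, "ranges.csv")),
    pas = read_rects_table(file.path(dir, "pas.csv")),
    islands = read_rects_table(file.path(dir, "islands.csv")),
    eradications = read_eradications(file.path(dir, "eradications.csv")),
    listings = read_listings(file.path(dir, "listings.csv")),
    taxonomy = read_taxonomy(file.path(dir, "taxonomy.csv")),
    points = read_points(file.path(dir, "points.csv")),
    countries = readr::read_csv(file.path(dir, "countries.csv"),
                                comment = "#", show_col_types = FALSE))
  meta <- yaml::read_yaml(file.path(dir, "world.yaml"))
  out <- list(grid = grid, stack = cg_stack(grid, layers, dem),
              tables = tables, meta = meta)
  gt <- file.path(dir, "ground_truth.csv")
  if (file.exists(gt))
    out$ground_truth <- readr::read_csv(gt, comment = "#",
                                        show_col_types = FALSE)
  out
}
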