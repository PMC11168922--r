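# Area of habitat, protected-area overlap, representation thresholds,
# Species Protection Scores and the meaningful-protection determination.

presence_codes <- function() {
  c("extant", "probably_extant", "possibly_extinct", "extinct",
    "presence_uncertain")
}
# presence codes making up the current (mapped) range used for AOH/SPS;
# the full set defines the historical range used for the island test
current_presence_codes <- function() c("extant", "probably_extant")

#' Species-specific representation threshold
#'
#' The minimum percentage of a species' habitat that must fall within
#' protected areas for the species to count as meaningfully represented:
#' 100% for areas up to 10,000 km2, 15% for areas of 250,000 km2 or more,
#' and a log-linear interpolation (linear in log10 area) between those two
#' anchor points otherwise. Continuous and non-increasing in area. Species
#' with less habitat need proportionally more of it protected.
#'
#' @param area_km2 numeric vector of nonnegative areas (km2).
#' @return numeric vector of thresholds in `[15, 100]` (percent).
#' @examples
#' representation_threshold(c(5e3, 5e4, 3e5))
#' @export
representation_threshold <- function(area_km2) {
  if (any(!is.finite(area_km2)) || any(area_km2 < 0))
    stop("area_km2 must be finite and nonnegative", call. = FALSE)
  lo <- 1e4; hi <- 2.5e5
  out <- rep(NA_real_, length(area_km2))
  out[area_km2 <= lo] <- 100
  out[area_km2 >= hi] <- 15
  mid <- is.na(out)
  out[mid] <- 100 - 85 * (log10(area_km2[mid]) - log10(lo)) / (log10(hi) - log10(lo))
  out
}

#' Species Protection Score
#'
#' The percentage of a species' range inside protected areas relative to
#' its representation threshold, capped at 100: `min(100, 100 * overlap /
#' threshold)`. A score of 100 means the species meets its species-specific
#' representation target; for example an overlap of 50% against a threshold
#' of 80% scores (50/80) x 100 = 62.5.
#'
#' @param overlap_pct percent of the range inside PAs, in `[0, 100]`.
#' @param threshold_pct representation threshold, in `(0, 100]`.
#' @return numeric vector of scores in `[0, 100]`.
#' @examples
#' species_protection_score(50, 80) # 62.5
#' species_protection_score(50, 50) # 100
#' @export
species_protection_score <- function(overlap_pct, threshold_pct) {
  if (any(!is.finite(overlap_pct)) || any(overlap_pct < 0 | overlap_pct > 100))
    stop("overlap_pct must be in [0, 100]", call. = FALSE)
  if (any(!is.finite(threshold_pct)) || any(threshold_pct <= 0 | threshold_pct > 100))
    stop("threshold_pct must be in (0, 100]", call. = FALSE)
  pmin(100, overlap_pct / threshold_pct * 100)
}

# numerical tolerance for the sps == 100 test: overlap within 1e-9 of the
# threshold counts as meeting it, so float noise cannot flip the binary
sps_meets_target <- function(overlap_pct, threshold_pct) {
  overlap_pct >= threshold_pct - 1e-9
}

#' Habitat/elevation raster stack
#'
#' Bundles the fractional habitat-class layers and the elevation model on a
#' common grid. `layers` is a named list of `nx` by `ny` matrices with
#' values in `[0, 1]` (fraction of the cell covered by that habitat
#' class), named by habitat classification code (e.g. `"1.4"`); `dem` is an
#' `nx` by `ny` matrix of elevations in metres.
#'
#' @param grid a [cg_grid()].
#' @param layers named list of fractional habitat matrices.
#' @param dem elevation matrix (metres), same dimensions.
#' @return object of class `cg_stack`.
#' @export
cg_stack <- function(grid, layers, dem) {
  stopifnot(inherits(grid, "cg_grid"), is.list(layers), length(layers) > 0,
            !is.null(names(layers)), all(nzchar(names(layers))))
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (!is.matrix(m) || nrow(m) != grid$nx || ncol(m) != grid$ny)
      stop("habitat layer '", nm, "' is not aligned with the grid", call. = FALSE)
    if (any(m < 0 | m > 1)) stop("habitat fractions must be in [0, 1]", call. = FALSE)
  }
  if (!is.matrix(dem) || nrow(dem) != grid$nx || ncol(dem) != grid$ny)
    stop("elevation raster is not aligned with the grid", call. = FALSE)
  structure(list(grid = grid, layers = layers, dem = dem), class = "cg_stack")
}

#' @export
print.cg_stack <- function(x, ...) {
  cat(sprintf("<cg_stack> %d habitat classes + DEM on %d x %d grid\n",
              length(x$layers), x$grid$nx, x$grid$ny))
  invisible(x)
}

# Expand level-1 habitat codes to all nested level-2 codes present in the
# stack; exact codes are kept as-is. "Forest" coded as "1" therefore
# matches "1", "1.4", "1.6", ...
expand_habitat_codes <- function(codes, available) {
  out <- character(0)
  for (cd in codes) {
    if (grepl(".", cd, fixed = TRUE)) {
      out <- c(out, cd)
    } else {
      out <- c(out, cd, available[grepl(paste0("^", cd, "\\."), available)])
    }
  }
  intersect(unique(out), available)
}

#' Compute area of habitat (AOH)
#'
#' Refines a species' range to its area of habitat (habitat-suitable
#' range): per cell, the suitable fraction is the summed fractional cover
#' of the species' suitable habitat classes (capped at 1), zeroed outside
#' the species' elevation limits and outside the rasterized range
#' (cell-centre membership). AOH area is the sum of suitable fractions
#' times the cell area. Level-1 habitat codes conservatively expand to all
#' nested level-2 classes; a species listing no habitat preference treats
#' all classes as suitable, so only range and elevation refine.
#'
#' @param range_rects rectangle table for the species' current range
#'   (see [cg_rects()]); may be empty (AOH is then 0).
#' @param habitat_codes character vector of suitable habitat codes
#'   (level 1 or 2); empty or `NULL` means all classes suitable.
#' @param elev_min,elev_max elevation limits in metres; `NA` = unbounded.
#' @param stack a [cg_stack()] with habitat layers and DEM.
#' @return list with `aoh` (an `nx` by `ny` matrix of suitable fractions)
#'   and `area_km2` (scalar).
#' @export
compute_aoh <- function(range_rects, habitat_codes, elev_min, elev_max, stack) {
  grid <- stack$grid
  zero <- matrix(0, grid$nx, grid$ny)
  if (is.null(range_rects) || nrow(range_rects) == 0)
    return(list(aoh = zero, area_km2 = 0))
  if (is.null(habitat_codes) || length(habitat_codes) == 0) {
    suit <- matrix(1, grid$nx, grid$ny)
  } else {
    use <- expand_habitat_codes(habitat_codes, names(stack$layers))
    suit <- zero
    for (nm in use) suit <- suit + stack$layers[[nm]]
    suit <- pmin(suit, 1)
  }
  elev_ok <- matrix(TRUE, grid$nx, grid$ny)
  if (!is.na(elev_min)) elev_ok <- elev_ok & stack$dem >= elev_min
  if (!is.na(elev_max)) elev_ok <- elev_ok & stack$dem <= elev_max
  in_range <- cells_in_rects(range_rects, grid)
  aoh <- suit * elev_ok * in_range
  list(aoh = aoh, area_km2 = sum(aoh) * cell_area_km2(grid))
}

#' Protected-area overlap of an AOH surface
#'
#' Percentage of the AOH (area-weighted) that falls inside protected
#' areas, using fractional per-cell PA coverage: `100 * sum(aoh * pa) /
#' sum(aoh)`.
#'
#' @param aoh an `nx` by `ny` matrix of suitable fractions (from
#'   [compute_aoh()], or a 0/1 membership matrix for an unrefined range).
#' @param pa_cov an `nx` by `ny` matrix of fractional PA coverage (from
#'   [coverage_fraction()]).
#' @return overlap percent in `[0, 100]`, or `NA_real_` when the AOH is
#'   empty (the zero-AOH condition; see [zero_aoh_fallback()]).
#' @export
pa_overlap_fraction <- function(aoh, pa_cov) {
  stopifnot(is.matrix(aoh), is.matrix(pa_cov), all(dim(aoh) == dim(pa_cov)))
  tot <- sum(aoh)
  if (tot == 0) return(NA_real_)
  min(100, 100 * sum(aoh * pa_cov) / tot)
}

#' Occurrence-point fallback for zero-AOH species
#'
#' Input-data limitations can leave a species with zero AOH. Such a species
#' is still credited with PA occurrence if a recent occurrence record —
#' observed within the last five years and buffered by 300 m for
#' positional error — intersects a protected area.
#'
#' @param points tibble of occurrence points with columns `x`, `y` (km)
#'   and `year`; may have zero rows.
#' @param pa_rects rectangle table of protected areas.
#' @param reference_year the year relative to which "the last five years"
#'   is evaluated (records with `year >= reference_year - 5` qualify).
#' @param buffer_km buffer radius in km (default 0.3 = 300 m).
#' @return single logical.
#' @export
zero_aoh_fallback <- function(points, pa_rects, reference_year,
                              buffer_km = 0.3) {
  if (is.null(points) || nrow(points) == 0) return(FALSE)
  recent <- points[points$year >= reference_year - 5, , drop = FALSE]
  if (nrow(recent) == 0) return(FALSE)
  d <- point_rect_distance(recent$x, recent$y, pa_rects)
  any(d <= buffer_km)
}

#' Meaningful habitat protection for one species
#'
#' Scores the species against its representation target on up to two
#' bases: the unrefined expert range (cell-centre rasterization of the
#' range rectangles) and the habitat-suitable range (AOH). Each basis uses
#' its own area for the representation threshold. The species is
#' meaningfully protected if *either* Species Protection Score is 100 (the
#' conservative reading). When the AOH is zero and no computed score
#' reaches 100, the determination is delegated to the occurrence-point
#' fallback and `basis` is `"point_fallback"`.
#'
#' @param range_rects current-range rectangles (presence extant or
#'   probably extant); may be empty only if `points` is non-empty.
#' @param habitat_codes,elev_min,elev_max species habitat/elevation
#'   preferences (see [compute_aoh()]).
#' @param stack a [cg_stack()].
#' @param pa_cov fractional PA coverage matrix on the same grid.
#' @param pa_rects PA rectangles (for the point fallback).
#' @param points occurrence points for the species (may be `NULL`).
#' @param reference_year reference year for the point fallback.
#' @return one-row tibble: `aoh_area_km2`, `overlap_pct`, `threshold_pct`,
#'   `sps`, `meaningful`, `basis`. The reported `overlap_pct`,
#'   `threshold_pct` and `sps` belong to the best-scoring computed basis.
#' @export
meaningful_protection <- function(range_rects, habitat_codes, elev_min,
                                  elev_max, stack, pa_cov, pa_rects,
                                  points = NULL, reference_year = NULL) {
  grid <- stack$grid
  have_range <- !is.null(range_rects) && nrow(range_rects) > 0
  have_points <- !is.null(points) && nrow(points) > 0
  if (!have_range && !have_points)
    stop("no range data: species has neither range geometry nor occurrence points",
         call. = FALSE)

  sps_expert <- NA_real_; ov_expert <- NA_real_; thr_expert <- NA_real_
  if (have_range) {
    member <- cells_in_rects(range_rects, grid)
    range_area <- sum(member) * cell_area_km2(grid)
    if (range_area > 0) {
      ov_expert <- pa_overlap_fraction(member * 1, pa_cov)
      thr_expert <- representation_threshold(range_area)
      sps_expert <- species_protection_score(ov_expert, thr_expert)
      if (sps_meets_target(ov_expert, thr_expert)) sps_expert <- 100
    }
  }

  res_aoh <- compute_aoh(range_rects, habitat_codes, elev_min, elev_max, stack)
  aoh_area <- res_aoh$area_km2
  sps_hsr <- NA_real_; ov_hsr <- NA_real_; thr_hsr <- NA_real_
  if (aoh_area > 0) {
    ov_hsr <- pa_overlap_fraction(res_aoh$aoh, pa_cov)
    thr_hsr <- representation_threshold(aoh_area)
    sps_hsr <- species_protection_score(ov_hsr, thr_hsr)
    if (sps_meets_target(ov_hsr, thr_hsr)) sps_hsr <- 100
  }

  computed <- c(expert_range = sps_expert, hsr = sps_hsr)
  any_computed <- any(!is.na(computed))
  meaningful <- any_computed && any(computed == 100, na.rm = TRUE)
  basis <- if (all(!is.na(computed))) "either"
           else if (any_computed) names(computed)[!is.na(computed)]
           else "point_fallback"

  # zero AOH and no computed score reached 100: the point fallback decides
  if (!meaningful && aoh_area == 0 && !is.null(reference_year)) {
    if (zero_aoh_fallback(points, pa_rects, reference_year)) {
      meaningful <- TRUE
      basis <- "point_fallback"
    }
  }

  # report the best-scoring computed basis' numbers (prefer HSR on ties)
  if (any_computed) {
    pick <- if (!is.na(sps_hsr) && (is.na(sps_expert) || sps_hsr >= sps_expert))
      "hsr" else "expert_range"
    ov <- if (pick == "hsr") ov_hsr else ov_expert
    thr <- if (pick == "hsr") thr_hsr else thr_expert
    sps <- if (pick == "hsr") sps_hsr else sps_expert
  } else {
    ov <- NA_real_; thr <- NA_real_; sps <- NA_real_
  }

  tibble::tibble(aoh_area_km2 = aoh_area, overlap_pct = ov,
                 threshold_pct = thr, sps = sps,
                 meaningful = meaningful, basis = basis)
}

#' Protection results for a species table
#'
#' Vector driver for [meaningful_protection()]: computes the PA coverage
#' surface once and scores every species.
#'
#' @param species species table (`taxon_id`, `habitat_codes`,
#'   `elevation_min_m`, `elevation_max_m`, ...).
#' @param ranges range rectangle table (`taxon_id`, `xmin`, `ymin`,
#'   `xmax`, `ymax`, `presence`).
#' @param stack a [cg_stack()].
#' @param pa_rects protected-area rectangles.
#' @param points occurrence-point table (`taxon_id`, `x`, `y`, `year`),
#'   may be `NULL`.
#' @param reference_year reference year for the point fallback.
#' @return tibble: one row per species with `taxon_id` and the
#'   [meaningful_protection()] columns. Species with no geometry and no
#'   points get `meaningful = FALSE`, `basis = "no_range_data"`.
#' @export
protection_table <- function(species, ranges, stack, pa_rects,
                             points = NULL, reference_year = NULL) {
  grid <- stack$grid
  pa_cov <- coverage_fraction(pa_rects, grid)
  cur <- ranges[ranges$presence %in% current_presence_codes(), , drop = FALSE]
  rows <- vector("list", nrow(species))
  for (i in seq_len(nrow(species))) {
    id <- species$taxon_id[i]
    rr <- cur[cur$taxon_id == id, , drop = FALSE]
    pts <- if (!is.null(points)) points[points$taxon_id == id, , drop = FALSE]
    codes <- split_codes(species$habitat_codes[i])[[1]]
    row <- tryCatch(
      meaningful_protection(rr, codes,
                            species$elevation_min_m[i], species$elevation_max_m[i],
                            stack, pa_cov, pa_rects, pts, reference_year),
      error = function(e) {
        tibble::tibble(aoh_area_km2 = 0, overlap_pct = NA_real_,
                       threshold_pct = NA_real_, sps = NA_real_,
                       meaningful = FALSE, basis = "no_range_data")
      })
    rows[[i]] <- dplyr::bind_cols(tibble::tibble(taxon_id = id), row)
  }
  dplyr::bind_rows(rows)
}
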