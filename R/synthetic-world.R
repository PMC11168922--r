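# Synthetic-world generator: complete input bundles (rasters, geometries,
# tables) with planted ground truth, so every pipeline stage is testable
# end-to-end without any external data.
#
# The ground-truth labels in this file are deliberately computed with
# generator-local brute-force code (naive per-cell loops, interval sweeps,
# stats::approx for the threshold curve) and never by calling the pipeline
# modules; exact label recovery by the pipeline is therefore a real
# end-to-end check.

#' Configuration for a synthetic world
#'
#' The defaults describe a world in which the pipeline's behaviour mirrors
#' the real study conditions at desk scale: a planar equal-area grid of
#' 100-km cells (cell area 10,000 km2, the small-range anchor of the
#' representation-threshold curve), species range sizes drawn log-uniform
#' across both threshold anchors (10^3 to 10^6 km2), about 15% of the
#' world under protected areas, six fractional habitat classes (Dirichlet
#' per cell), a smooth elevation surface, Red List-style threat coding
#' probabilities, and a planted apparent-neglect proportion of 0.58.
#'
#' @param grid_nx,grid_ny,cell_km grid shape; cell edge in km.
#' @param n_species number of threatened species to generate.
#' @param class_probs named probabilities over taxonomic classes.
#' @param category_probs named probabilities over VU/EN/CR.
#' @param possibly_extinct_prob probability that a CR species is flagged
#'   Possibly Extinct.
#' @param range_km2 length-2: log-uniform range-size interval (km2).
#' @param pa_coverage approximate fraction of the world under PAs.
#' @param n_pa number of protected-area rectangles.
#' @param habitat_classes level-2 habitat codes carried by the landscape.
#' @param habitat_pref_prob probability a species lists habitat
#'   preferences (otherwise all classes are suitable).
#' @param elevation_amplitude_m amplitude of the smooth elevation field.
#' @param elevation_pref_prob probability a species has elevation limits.
#' @param island_fraction fraction of species that are island species.
#' @param n_islands number of (disjoint) islands.
#' @param island_invasive_threat_prob probability an island species
#'   carries an invasive-species threat record with a named invasive
#'   vertebrate (invasive species are the dominant threat on islands).
#' @param threat_rate mean number of threat records per species (>= 1).
#' @param scope_probs,severity_probs,timing_probs named sampling
#'   probabilities for the threat coding fields.
#' @param ecosystem_stress_prob probability a habitat-type threat record
#'   carries an ecosystem/community stress code.
#' @param trade_flag_prob probability an overexploitation record is
#'   flagged intentional-use/international-trade.
#' @param evidence_tabular_prob,evidence_text_prob per-category flag
#'   probabilities for species that are not planted as neglected.
#' @param cites_listing_prob,genus_listing_prob probabilities of planting
#'   species- or genus-level CITES listings (non-neglected species only).
#' @param cms_listing_prob probability of planting a CMS listing.
#' @param eradication_prob probability an eligible island species gets a
#'   successful eradication of its named invasive.
#' @param neglect_prob planted probability that a species lacks any
#'   documented intervention (the apparent-neglect proportion).
#' @param n_countries number of countries (vertical bands of the world).
#' @param points_recent_prob probability a non-neglected zero-AOH species
#'   gets a recent in-PA occurrence point (exercising the fallback).
#' @param reference_year dataset reference year (for the 5-year window).
#' @param n_status_changes,nongenuine_prob,reversal_prob,multi_prob,downlist_prob
#'   status-change generation: number of taxa with changes and the
#'   probabilities of non-genuine records, genuine-then-nongenuine
#'   reversals, multiple genuine changes, and downlists.
#' @return validated config list of class `cg_world_config`.
#' @export
synthetic_world_config <- function(
    grid_nx = 40, grid_ny = 40, cell_km = 100,
    n_species = 300,
    class_probs = c(Amphibia = 0.35, Aves = 0.25, Mammalia = 0.20,
                    Magnoliopsida = 0.20),
    category_probs = c(VU = 0.40, EN = 0.35, CR = 0.25),
    possibly_extinct_prob = 0.08,
    range_km2 = c(1e3, 1e6),
    pa_coverage = 0.15, n_pa = 60,
    habitat_classes = c("1.1", "1.2", "1.3", "2.1", "2.2", "3.1"),
    habitat_pref_prob = 0.8,
    elevation_amplitude_m = 3000,
    elevation_pref_prob = 0.5,
    island_fraction = 0.12, n_islands = 8,
    island_invasive_threat_prob = 0.6,
    threat_rate = 2,
    scope_probs = c(minority_lt50 = 0.25, majority_gt50 = 0.30,
                    whole = 0.25, unknown = 0.20),
    severity_probs = c(negligible = 0.10, slow_significant = 0.30,
                       rapid = 0.25, very_rapid = 0.15,
                       fluctuating = 0.05, unknown = 0.15),
    timing_probs = c(past = 0.10, ongoing = 0.70, future = 0.10,
                     unknown = 0.10),
    ecosystem_stress_prob = 0.7,
    trade_flag_prob = 0.6,
    evidence_tabular_prob = 0.25, evidence_text_prob = 0.15,
    cites_listing_prob = 0.3, genus_listing_prob = 0.1,
    cms_listing_prob = 0.1,
    eradication_prob = 0.5,
    neglect_prob = 0.58,
    n_countries = 8,
    points_recent_prob = 0.5,
    reference_year = 2020,
    n_status_changes = 60, nongenuine_prob = 0.2, reversal_prob = 0.1,
    multi_prob = 0.1, downlist_prob = 0.15) {
  cfg <- as.list(environment())
  class(cfg) <- "cg_world_config"
  validate_world_config(cfg)
  cfg
}

validate_world_config <- function(cfg) {
  bad <- character(0)
  prob_fields <- c("possibly_extinct_prob", "pa_coverage",
                   "habitat_pref_prob", "elevation_pref_prob",
                   "island_fraction", "ecosystem_stress_prob",
                   "trade_flag_prob", "evidence_tabular_prob",
                   "evidence_text_prob", "cites_listing_prob",
                   "genus_listing_prob", "cms_listing_prob",
                   "eradication_prob", "neglect_prob", "points_recent_prob",
                   "island_invasive_threat_prob",
                   "nongenuine_prob", "reversal_prob", "multi_prob",
                   "downlist_prob")
  for (f in prob_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) bad <- c(bad, f)
  }
  for (f in c("class_probs", "category_probs", "scope_probs",
              "severity_probs", "timing_probs")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || any(v < 0) || abs(sum(v) - 1) > 1e-8) bad <- c(bad, f)
  }
  if (!(length(cfg$range_km2) == 2 && all(cfg$range_km2 > 0) &&
        cfg$range_km2[1] < cfg$range_km2[2])) bad <- c(bad, "range_km2")
  for (f in c("grid_nx", "grid_ny", "n_species", "n_pa", "n_islands",
              "n_countries", "n_status_changes")) {
    if (!(is.numeric(cfg[[f]]) && cfg[[f]] >= 1)) bad <- c(bad, f)
  }
  if (!(is.numeric(cfg$threat_rate) && cfg$threat_rate >= 1))
    bad <- c(bad, "threat_rate")
  if (length(bad) > 0)
    stop("invalid synthetic-world config field(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  invisible(cfg)
}

# ---- generator-local brute-force helpers (independent of the pipeline) ----

# exact union area of a set of rectangles clipped to a window, by x-sweep
# with y-interval merging (a different algorithm from the pipeline's atom
# decomposition)
gt_union_area_in_window <- function(rects, wx0, wx1, wy0, wy1) {
  if (nrow(rects) == 0) return(0)
  x0 <- pmax(rects$xmin, wx0); x1 <- pmin(rects$xmax, wx1)
  y0 <- pmax(rects$ymin, wy0); y1 <- pmin(rects$ymax, wy1)
  keep <- x0 < x1 & y0 < y1
  if (!any(keep)) return(0)
  x0 <- x0[keep]; x1 <- x1[keep]; y0 <- y0[keep]; y1 <- y1[keep]
  xs <- sort(unique(c(x0, x1)))
  total <- 0
  for (s in seq_len(length(xs) - 1)) {
    xa <- xs[s]; xb <- xs[s + 1]
    act <- x0 <= xa & x1 >= xb
    if (!any(act)) next
    iv <- cbind(y0[act], y1[act])
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    cov <- 0; cur_lo <- iv[1, 1]; cur_hi <- iv[1, 2]
    if (nrow(iv) > 1) for (k in 2:nrow(iv)) {
      if (iv[k, 1] > cur_hi) {
        cov <- cov + (cur_hi - cur_lo)
        cur_lo <- iv[k, 1]; cur_hi <- iv[k, 2]
      } else cur_hi <- max(cur_hi, iv[k, 2])
    }
    cov <- cov + (cur_hi - cur_lo)
    total <- total + cov * (xb - xa)
  }
  total
}

# fractional PA coverage per cell, cell by cell
gt_pa_fraction <- function(pa, grid_nx, grid_ny, cell_km) {
  out <- matrix(0, grid_nx, grid_ny)
  for (ix in seq_len(grid_nx)) for (iy in seq_len(grid_ny)) {
    wx0 <- (ix - 1) * cell_km; wy0 <- (iy - 1) * cell_km
    a <- gt_union_area_in_window(pa, wx0, wx0 + cell_km, wy0, wy0 + cell_km)
    out[ix, iy] <- a / cell_km^2
  }
  out
}

# representation threshold via stats::approx between the two anchors
gt_threshold <- function(area_km2) {
  stats::approx(x = log10(c(1e4, 2.5e5)), y = c(100, 15),
                xout = log10(max(area_km2, 1)), rule = 2)$y
}

gt_sps_meets <- function(overlap_pct, threshold_pct) {
  overlap_pct >= threshold_pct - 1e-9
}

# brute-force protection assessment for one species (single range rect)
gt_protection <- function(rect, hab_pref, emin, emax, layers, dem, pa_frac,
                          cell_km) {
  nx <- nrow(dem); ny <- ncol(dem)
  cellarea <- cell_km^2
  member <- matrix(FALSE, nx, ny)
  for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
    cx <- (ix - 0.5) * cell_km; cy <- (iy - 0.5) * cell_km
    member[ix, iy] <- cx >= rect$xmin && cx < rect$xmax &&
      cy >= rect$ymin && cy < rect$ymax
  }
  n_member <- sum(member)
  expert_meets <- FALSE; expert_area <- n_member * cellarea
  if (n_member > 0) {
    ov <- 100 * sum(pa_frac[member]) / n_member
    expert_meets <- gt_sps_meets(ov, gt_threshold(expert_area))
    expert_margin <- gt_threshold(expert_area) - ov
  } else expert_margin <- Inf
  # suitable classes: level-1 prefs expand by prefix
  if (length(hab_pref) == 0) {
    suit_codes <- names(layers)
  } else {
    suit_codes <- character(0)
    for (cd in hab_pref) {
      if (grepl(".", cd, fixed = TRUE)) suit_codes <- c(suit_codes, cd)
      else suit_codes <- c(suit_codes,
                           names(layers)[startsWith(names(layers),
                                                    paste0(cd, "."))])
    }
    suit_codes <- intersect(unique(suit_codes), names(layers))
  }
  aoh <- matrix(0, nx, ny)
  for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
    if (!member[ix, iy]) next
    f <- 0
    for (cd in suit_codes) f <- f + layers[[cd]][ix, iy]
    f <- min(f, 1)
    e <- dem[ix, iy]
    if (!is.na(emin) && e < emin) f <- 0
    if (!is.na(emax) && e > emax) f <- 0
    aoh[ix, iy] <- f
  }
  aoh_area <- sum(aoh) * cellarea
  hsr_meets <- FALSE; hsr_margin <- Inf
  if (aoh_area > 0) {
    ov <- 100 * sum(aoh * pa_frac) / sum(aoh)
    hsr_meets <- gt_sps_meets(ov, gt_threshold(aoh_area))
    hsr_margin <- gt_threshold(aoh_area) - ov
  }
  list(expert_meets = expert_meets, hsr_meets = hsr_meets,
       aoh_area = aoh_area, expert_area = expert_area,
       margin = min(expert_margin, hsr_margin))
}

sample1 <- function(x, probs) sample(x, 1, prob = probs)

#' Generate a complete synthetic world
#'
#' Builds the landscape (fractional habitat layers, smooth elevation
#' surface, protected areas, islands, country bands), a full set of
#' species with Red List-style threat records, intervention evidence,
#' listings, eradication events and occurrence points — and a ground-truth
#' table of planted labels. Species are planted as "neglected" (no
#' documented intervention) independently with probability
#' `config$neglect_prob`; neglected species carry no evidence, no
#' qualifying listings or eradications, and their ranges are placed (by
#' rejection) so that their PA overlap sits clearly below the
#' representation threshold on both scoring bases. Non-neglected species
#' are guaranteed at least one documented intervention. Deterministic for
#' a fixed seed.
#'
#' @param config a [synthetic_world_config()].
#' @param seed integer random seed.
#' @return list: `grid`, `stack` (habitat + DEM), `tables` (species,
#'   threats, evidence, ranges, pas, islands, eradications, listings,
#'   taxonomy, points, countries), `ground_truth`, `config`, `seed`.
#' @export
generate_world <- function(config = synthetic_world_config(), seed = 1) {
  validate_world_config(config)
  set.seed(seed)
  nx <- config$grid_nx; ny <- config$grid_ny; cell <- config$cell_km
  wx <- nx * cell; wy <- ny * cell
  grid <- cg_grid(nx, ny, cell)

  # habitat: Dirichlet fractions per cell over the classes
  k <- length(config$habitat_classes)
  g <- matrix(stats::rgamma(nx * ny * k, shape = 1.2), ncol = k)
  g <- g / rowSums(g)
  layers <- list()
  for (j in seq_len(k))
    layers[[config$habitat_classes[j]]] <- matrix(g[, j], nx, ny)

  # smooth elevation surface from a few sinusoidal bumps
  xs <- (seq_len(nx) - 0.5) / nx; ys <- (seq_len(ny) - 0.5) / ny
  dem <- matrix(0, nx, ny)
  for (b in 1:4) {
    fx <- runif(1, 0.5, 2.5); fy <- runif(1, 0.5, 2.5)
    px <- runif(1, 0, 2 * pi); py <- runif(1, 0, 2 * pi)
    dem <- dem + outer(sin(2 * pi * fx * xs + px), sin(2 * pi * fy * ys + py))
  }
  dem <- (dem - min(dem)) / (max(dem) - min(dem)) * config$elevation_amplitude_m

  # disjoint islands in fixed slots along the southern margin
  n_isl <- config$n_islands
  slot_w <- wx / n_isl
  isl_rows <- list()
  for (j in seq_len(n_isl)) {
    iw <- runif(1, 0.25, 0.6) * slot_w
    ih <- runif(1, 0.1, 0.25) * wy
    x0 <- (j - 1) * slot_w + runif(1, 0, slot_w - iw)
    y0 <- runif(1, 0, 0.3 * wy - ih)
    isl_rows[[j]] <- tibble::tibble(island_id = sprintf("ISL%02d", j),
                                    xmin = x0, ymin = y0,
                                    xmax = x0 + iw, ymax = y0 + ih)
  }
  islands <- dplyr::bind_rows(isl_rows)

  # protected areas: random rectangles until the area budget is met;
  # full coverage is represented exactly by one world-spanning PA
  target <- config$pa_coverage * wx * wy
  pa_rows <- list(); placed <- 0
  if (config$pa_coverage >= 1) {
    pa_rows[[1]] <- tibble::tibble(pa_id = "PA001", xmin = 0, ymin = 0,
                                   xmax = wx, ymax = wy)
    placed <- target
  } else for (j in seq_len(config$n_pa)) {
    if (placed >= target) break
    a <- exp(runif(1, log(target / config$n_pa / 4), log(target / config$n_pa * 4)))
    asp <- runif(1, 0.5, 2)
    w <- sqrt(a * asp); h <- a / w
    w <- min(w, wx * 0.9); h <- min(h, wy * 0.9)
    x0 <- runif(1, 0, wx - w); y0 <- runif(1, 0, wy - h)
    pa_rows[[j]] <- tibble::tibble(pa_id = sprintf("PA%03d", j),
                                   xmin = x0, ymin = y0,
                                   xmax = x0 + w, ymax = y0 + h)
    placed <- placed + a
  }
  pas <- dplyr::bind_rows(pa_rows)
  pa_frac <- gt_pa_fraction(pas, nx, ny, cell)

  # countries: vertical bands
  n_cty <- config$n_countries
  cty_codes <- sprintf("C%02d", seq_len(n_cty))
  band_w <- wx / n_cty
  countries <- tibble::tibble(
    country = cty_codes,
    xmin = (seq_len(n_cty) - 1) * band_w, xmax = seq_len(n_cty) * band_w,
    gdp = exp(rnorm(n_cty, mean = 26, sd = 1.5)))

  classes <- names(config$class_probs)
  families <- paste0(rep(classes, each = 3), "idae", rep(1:3, length(classes)))
  invasive_pool <- c("Rattus rattus", "Felis catus", "Capra hircus",
                     "Sus scrofa", "Mustela erminea", "Oryctolagus cuniculus")
  mapping_file <- system.file("extdata", "cbd_threat_mapping.csv",
                              package = "consgap")
  map_raw <- utils::read.csv(mapping_file, stringsAsFactors = FALSE)
  map_raw$code <- as.character(map_raw$code)
  lvl2 <- map_raw[grepl(".", map_raw$code, fixed = TRUE), ]

  n <- config$n_species
  sp_rows <- list(); thr_rows <- list(); ev_rows <- list()
  rng_rows <- list(); lst_rows <- list(); erad_rows <- list()
  tax_rows <- list(); pt_rows <- list(); gt_rows <- list()
  erad_counter <- 0
  # islands already hosting a successful eradication of a given invasive:
  # never let a *neglected* island species keep that invasive in its named
  # list (it would gain invasive control through the eradication route)
  erad_on_island <- list()
  # neglected island species placed so far, to guard later eradication
  # planting against retroactively granting them invasive control
  negl_guard <- list()

  # exact overlap of a single rectangle with the (disjoint) islands
  island_overlap_area <- function(rect) {
    ox <- pmax(0, pmin(rect$xmax, islands$xmax) - pmax(rect$xmin, islands$xmin))
    oy <- pmax(0, pmin(rect$ymax, islands$ymax) - pmax(rect$ymin, islands$ymin))
    sum(ox * oy)
  }

  for (i in seq_len(n)) {
    id <- sprintf("SP%04d", i)
    cls <- sample1(classes, config$class_probs)
    fam <- sample1(families[startsWith(families, cls)], NULL)
    cat_rl <- sample1(names(config$category_probs), config$category_probs)
    pex <- cat_rl == "CR" && runif(1) < config$possibly_extinct_prob
    neglected <- runif(1) < config$neglect_prob
    is_island <- runif(1) < config$island_fraction

    # habitat / elevation preferences
    if (runif(1) < config$habitat_pref_prob) {
      lvl1 <- unique(sub("\\..*", "", config$habitat_classes))
      pref <- unique(c(
        sample(config$habitat_classes, sample(1:3, 1)),
        if (runif(1) < 0.3) sample(lvl1, 1)))
    } else pref <- character(0)
    if (runif(1) < config$elevation_pref_prob) {
      emin <- runif(1, 0, config$elevation_amplitude_m * 0.5)
      emax <- emin + runif(1, 0.2, 0.8) * config$elevation_amplitude_m
    } else { emin <- NA_real_; emax <- NA_real_ }

    # threats: ensure at least one record; draw codes from the level-2 map
    n_thr <- max(1, stats::rpois(1, config$threat_rate))
    named_inv <- character(0)
    sp_thr <- list()
    for (tix in seq_len(n_thr)) {
      code <- sample(lvl2$code, 1)
      raw_cat <- lvl2$cbd_category[lvl2$code == code]
      scope <- sample1(names(config$scope_probs), config$scope_probs)
      sev <- sample1(names(config$severity_probs), config$severity_probs)
      tim <- sample1(names(config$timing_probs), config$timing_probs)
      eco <- raw_cat == "habitat_loss" && runif(1) < config$ecosystem_stress_prob
      stresses <- if (eco) sample(c("1.1", "1.2", "1.3"), 1) else "2.1"
      trade_flag <- raw_cat == "overexploitation" && runif(1) < config$trade_flag_prob
      if (raw_cat == "invasive_species") {
        nm <- sample(invasive_pool, 1)
        named_inv <- unique(c(named_inv, nm))
      }
      sp_thr[[tix]] <- tibble::tibble(
        taxon_id = id, code = code, scope = scope, severity = sev,
        timing = tim, stresses = stresses, intentional_trade = trade_flag)
    }
    # island species very often face a named invasive vertebrate
    if (is_island && length(named_inv) == 0 &&
        runif(1) < config$island_invasive_threat_prob) {
      nm <- sample(invasive_pool, 1)
      named_inv <- nm
      sp_thr[[length(sp_thr) + 1]] <- tibble::tibble(
        taxon_id = id, code = "8.1",
        scope = sample1(names(config$scope_probs), config$scope_probs),
        severity = sample1(names(config$severity_probs), config$severity_probs),
        timing = sample1(names(config$timing_probs), config$timing_probs),
        stresses = "2.1", intentional_trade = FALSE)
    }
    sp_thr <- dplyr::bind_rows(sp_thr)
    thr_rows[[i]] <- sp_thr

    # ground-truth major threats: direct rule application (include_unknown
    # = TRUE, the default study condition)
    gt_major <- setNames(rep(FALSE, 6), cbd_categories())
    for (tix in seq_len(nrow(sp_thr))) {
      r <- sp_thr[tix, ]
      s_ok <- r$scope %in% c("majority_gt50", "whole", "unknown")
      v_ok <- r$severity %in% c("slow_significant", "rapid", "very_rapid", "unknown")
      t_ok <- r$timing %in% c("past", "ongoing")
      if (!(s_ok && v_ok && t_ok)) next
      rc <- lvl2$cbd_category[lvl2$code == r$code]
      if (rc == "overexploitation")
        rc <- if (r$intentional_trade) "overexploitation_international_trade" else "other"
      if (rc == "habitat_loss" && !startsWith(r$stresses, "1")) next
      gt_major[rc] <- TRUE
    }

    # range placement
    place_range <- function() {
      a <- exp(runif(1, log(config$range_km2[1]), log(config$range_km2[2])))
      asp <- runif(1, 0.5, 2)
      w <- sqrt(a * asp); h <- a / w
      if (is_island) {
        isl <- islands[sample(nrow(islands), 1), ]
        iw <- isl$xmax - isl$xmin; ih <- isl$ymax - isl$ymin
        w <- min(w, iw * 0.95); h <- min(h, ih * 0.95)
        x0 <- runif(1, isl$xmin, isl$xmax - w)
        y0 <- runif(1, isl$ymin, isl$ymax - h)
        list(rect = tibble::tibble(xmin = x0, ymin = y0,
                                   xmax = x0 + w, ymax = y0 + h),
             island_id = isl$island_id)
      } else {
        w <- min(w, wx * 0.9); h <- min(h, wy * 0.9)
        x0 <- runif(1, 0, wx - w); y0 <- runif(1, 0, wy - h)
        list(rect = tibble::tibble(xmin = x0, ymin = y0,
                                   xmax = x0 + w, ymax = y0 + h),
             island_id = NA_character_)
      }
    }
    pl <- place_range()
    prot <- gt_protection(pl$rect, pref, emin, emax, layers, dem, pa_frac, cell)
    if (neglected) {
      tries <- 0
      # a neglected species must clearly miss its representation target on
      # every scored basis (margin >= 0.5 SPS percentage points)
      while ((prot$expert_meets || prot$hsr_meets || prot$margin < 0.5) &&
             tries < 300) {
        pl <- place_range()
        prot <- gt_protection(pl$rect, pref, emin, emax, layers, dem, pa_frac,
                              cell)
        tries <- tries + 1
      }
      if (prot$expert_meets || prot$hsr_meets || prot$margin < 0.5)
        stop("could not place a clearly unprotected range for planted ",
             "neglected species ", id,
             "; lower pa_coverage or enlarge the grid", call. = FALSE)
    }

    # geometric island status: strictly more than 95% of the range area on
    # islands, computed with exact rectangle overlaps
    rect_area_i <- (pl$rect$xmax - pl$rect$xmin) * (pl$rect$ymax - pl$rect$ymin)
    gt_island <- island_overlap_area(pl$rect) / rect_area_i > 0.95

    if (neglected && gt_island) {
      # strip invasives already eradicated on any island this range touches
      for (j in seq_len(nrow(islands))) {
        ox <- max(0, min(pl$rect$xmax, islands$xmax[j]) -
                    max(pl$rect$xmin, islands$xmin[j]))
        oy <- max(0, min(pl$rect$ymax, islands$ymax[j]) -
                    max(pl$rect$ymin, islands$ymin[j]))
        if (ox * oy > 0)
          named_inv <- setdiff(named_inv, erad_on_island[[islands$island_id[j]]])
      }
      negl_guard[[length(negl_guard) + 1]] <-
        list(rect = pl$rect, names = named_inv)
    }
    rng_rows[[i]] <- tibble::tibble(
      taxon_id = id, xmin = pl$rect$xmin, ymin = pl$rect$ymin,
      xmax = pl$rect$xmax, ymax = pl$rect$ymax, presence = "extant")

    gt_meaningful <- prot$expert_meets || prot$hsr_meets

    # occurrence points for zero-AOH species (the GBIF-style fallback)
    fallback <- FALSE
    if (prot$aoh_area == 0) {
      if (!neglected && runif(1) < config$points_recent_prob &&
          nrow(pas) > 0) {
        p <- pas[sample(nrow(pas), 1), ]
        pt_rows[[length(pt_rows) + 1]] <- tibble::tibble(
          taxon_id = id, x = (p$xmin + p$xmax) / 2,
          y = (p$ymin + p$ymax) / 2,
          year = config$reference_year - sample(0:4, 1))
        fallback <- TRUE
      } else if (runif(1) < 0.3 && nrow(pas) > 0) {
        # stale record inside a PA: must NOT trigger the fallback
        p <- pas[sample(nrow(pas), 1), ]
        pt_rows[[length(pt_rows) + 1]] <- tibble::tibble(
          taxon_id = id, x = (p$xmin + p$xmax) / 2,
          y = (p$ymin + p$ymax) / 2,
          year = config$reference_year - sample(7:15, 1))
      }
    }
    gt_meaningful <- gt_meaningful || (prot$aoh_area == 0 && fallback)

    # evidence flags
    cats <- intervention_categories()
    tab <- setNames(rep(FALSE, 6), cats); txt <- tab
    if (!neglected) {
      tab[] <- runif(6) < config$evidence_tabular_prob
      txt[] <- runif(6) < config$evidence_text_prob
    }

    # listings (non-neglected only; genus names are unique per species so
    # genus-level listings cannot leak onto other species)
    genus <- paste0("Genus_", i)
    has_cites <- FALSE; has_cms <- FALSE
    if (!neglected) {
      if (runif(1) < config$cites_listing_prob) {
        grp <- if (runif(1) < config$genus_listing_prob) genus else id
        lst_rows[[length(lst_rows) + 1]] <- tibble::tibble(
          group = grp, instrument = "CITES_appendix",
          instrument_detail = sample(c("I", "II"), 1))
        has_cites <- TRUE
      }
      if (runif(1) < config$cms_listing_prob) {
        lst_rows[[length(lst_rows) + 1]] <- tibble::tibble(
          group = id, instrument = "CMS", instrument_detail = "Appendix I")
        has_cms <- TRUE
      }
    }

    # eradications (non-neglected island species with a named invasive);
    # never plant one that would retroactively grant invasive control to a
    # previously placed neglected island species
    has_erad <- FALSE
    if (!neglected && gt_island && length(named_inv) > 0 &&
        runif(1) < config$eradication_prob && !is.na(pl$island_id)) {
      nm <- named_inv[1]
      isl <- islands[islands$island_id == pl$island_id, ]
      conflict <- FALSE
      for (gden in negl_guard) {
        if (!(nm %in% gden$names)) next
        ox <- max(0, min(gden$rect$xmax, isl$xmax) - max(gden$rect$xmin, isl$xmin))
        oy <- max(0, min(gden$rect$ymax, isl$ymax) - max(gden$rect$ymin, isl$ymin))
        if (ox * oy > 0) { conflict <- TRUE; break }
      }
      if (!conflict) {
        erad_counter <- erad_counter + 1
        erad_rows[[length(erad_rows) + 1]] <- tibble::tibble(
          island_id = pl$island_id, invasive_species_name = nm,
          outcome = "successful",
          year = sample(1990:config$reference_year, 1))
        erad_on_island[[pl$island_id]] <-
          unique(c(erad_on_island[[pl$island_id]], nm))
        has_erad <- TRUE
      }
    }

    # ground-truth intervention statuses (direct rule application)
    gt_pa_occ <- tab["pa_occurrence"] || txt["pa_occurrence"]
    gt_trade <- tab["trade_control"] || txt["trade_control"] || has_cites
    gt_invasive <- tab["invasive_control"] || txt["invasive_control"] ||
      has_erad
    gt_reintro <- tab["reintroduction"] || txt["reintroduction"]
    gt_legis <- tab["legislation"] || txt["legislation"] || gt_trade || has_cms
    gt_educ <- tab["education"] || txt["education"]
    gt_any <- gt_meaningful || gt_legis || gt_invasive || gt_reintro || gt_educ

    # guarantee the planted label: a non-neglected species that drew no
    # qualifying intervention gets one tabular flag forced on
    if (!neglected && !gt_any) {
      forced <- sample(c("legislation", "invasive_control", "reintroduction",
                         "education"), 1)
      tab[forced] <- TRUE
      if (forced == "legislation") gt_legis <- TRUE
      if (forced == "invasive_control") gt_invasive <- TRUE
      if (forced == "reintroduction") gt_reintro <- TRUE
      if (forced == "education") gt_educ <- TRUE
      gt_any <- TRUE
    }
    stopifnot(gt_any == !neglected)

    ev_rows[[i]] <- tibble::tibble(
      taxon_id = id,
      pa_occurrence_tabular = unname(tab["pa_occurrence"]),
      pa_occurrence_text = unname(txt["pa_occurrence"]),
      trade_control_tabular = unname(tab["trade_control"]),
      trade_control_text = unname(txt["trade_control"]),
      invasive_control_tabular = unname(tab["invasive_control"]),
      invasive_control_text = unname(txt["invasive_control"]),
      reintroduction_tabular = unname(tab["reintroduction"]),
      reintroduction_text = unname(txt["reintroduction"]),
      legislation_tabular = unname(tab["legislation"]),
      legislation_text = unname(txt["legislation"]),
      education_tabular = unname(tab["education"]),
      education_text = unname(txt["education"]))

    # countries = bands the range rectangle overlaps
    hit <- countries$country[countries$xmax > pl$rect$xmin &
                               countries$xmin < pl$rect$xmax]
    endemic <- if (length(hit) == 1) hit else NA_character_

    tax_rows[[i]] <- tibble::tibble(taxon_id = id, genus = genus,
                                    family = fam, class = cls)
    sp_rows[[i]] <- tibble::tibble(
      taxon_id = id, scientific_name = paste(genus, "sp."),
      taxon_class = cls, family = fam, redlist_category = cat_rl,
      possibly_extinct = pex, system = "terrestrial",
      habitat_codes = paste(pref, collapse = ";"),
      elevation_min_m = emin, elevation_max_m = emax,
      countries = paste(hit, collapse = ";"),
      endemic_country = endemic,
      evolutionary_distinctiveness = stats::rgamma(1, 1.5, scale = 5),
      named_invasives = paste(named_inv, collapse = ";"))

    gt_rows[[i]] <- tibble::tibble(
      taxon_id = id,
      major_habitat_loss = unname(gt_major["habitat_loss"]),
      major_trade = unname(gt_major["overexploitation_international_trade"]),
      major_pollution = unname(gt_major["pollution"]),
      major_invasive = unname(gt_major["invasive_species"]),
      major_climate = unname(gt_major["climate_change"]),
      major_other = unname(gt_major["other"]),
      pa_occurrence = gt_pa_occ, trade_control = gt_trade,
      invasive_control = gt_invasive, reintroduction = gt_reintro,
      legislation = gt_legis, education = gt_educ,
      meaningful_habitat_protection = gt_meaningful,
      island_species = gt_island,
      any_documented = gt_any, neglected = !gt_any,
      aoh_area_km2 = prot$aoh_area)
  }

  # post-pass: eradications planted later in the loop can credit earlier
  # species on the same island with the same named invasive — fold that
  # into the ground truth now that the eradication set is final (the
  # guards above guarantee no *neglected* species is affected)
  gt <- dplyr::bind_rows(gt_rows)
  sp <- dplyr::bind_rows(sp_rows)
  rng <- dplyr::bind_rows(rng_rows)
  for (i in seq_len(n)) {
    if (!gt$island_species[i] || gt$invasive_control[i]) next
    names_i <- strsplit(sp$named_invasives[i], ";", fixed = TRUE)[[1]]
    names_i <- names_i[nzchar(names_i)]
    if (length(names_i) == 0) next
    credited <- FALSE
    for (j in seq_len(nrow(islands))) {
      ox <- max(0, min(rng$xmax[i], islands$xmax[j]) -
                  max(rng$xmin[i], islands$xmin[j]))
      oy <- max(0, min(rng$ymax[i], islands$ymax[j]) -
                  max(rng$ymin[i], islands$ymin[j]))
      if (ox * oy > 0 &&
          any(names_i %in% erad_on_island[[islands$island_id[j]]])) {
        credited <- TRUE
        break
      }
    }
    if (credited) {
      stopifnot(!gt$neglected[i]) # the planting guards must have held
      gt$invasive_control[i] <- TRUE
    }
  }

  list(grid = grid,
       stack = cg_stack(grid, layers, dem),
       tables = list(
         species = sp,
         threats = dplyr::bind_rows(thr_rows),
         evidence = dplyr::bind_rows(ev_rows),
         ranges = rng,
         pas = pas,
         islands = islands,
         eradications = if (length(erad_rows)) dplyr::bind_rows(erad_rows)
           else tibble::tibble(island_id = character(0),
                               invasive_species_name = character(0),
                               outcome = character(0), year = integer(0)),
         listings = if (length(lst_rows)) dplyr::bind_rows(lst_rows)
           else tibble::tibble(group = character(0), instrument = character(0),
                               instrument_detail = character(0)),
         taxonomy = dplyr::bind_rows(tax_rows),
         points = if (length(pt_rows)) dplyr::bind_rows(pt_rows)
           else tibble::tibble(taxon_id = character(0), x = numeric(0),
                               y = numeric(0), year = integer(0)),
         countries = countries),
       ground_truth = gt,
       config = config, seed = seed)
}

#' Generate synthetic Red List status-change records
#'
#' Builds a status-change table that exercises every rule of the genuine
#' filter: plain genuine changes, non-genuine records, genuine changes
#' later superseded by a non-genuine reversal (both must be dropped — the
#' flying-fox pattern), and taxa with several genuine changes (only the
#' first survives). The expected post-filter table is constructed directly
#' during generation and returned alongside.
#'
#' @param config a [synthetic_world_config()].
#' @param seed integer seed.
#' @param taxon_ids optional pool of taxon ids to draw from (e.g. a
#'   generated world's species); defaults to fresh ids.
#' @return list with `records` (shuffled tibble: `taxon_id`, `year`,
#'   `from_category`, `to_category`, `reason`, `note`) and `expected`
#'   (tibble of the records that must survive [filter_genuine()], with a
#'   `direction` column).
#' @export
generate_status_changes <- function(config = synthetic_world_config(),
                                    seed = 1, taxon_ids = NULL) {
  validate_world_config(config)
  set.seed(seed + 1000003L)
  n <- config$n_status_changes
  if (is.null(taxon_ids))
    taxon_ids <- sprintf("SC%04d", seq_len(n))
  taxon_ids <- sample(taxon_ids, min(n, length(taxon_ids)))
  scale <- c("VU", "EN", "CR")
  recs <- list(); exp_rows <- list()
  mk <- function(id, year, from, to, reason) {
    tibble::tibble(taxon_id = id, year = year, from_category = from,
                   to_category = to, reason = reason, note = "")
  }
  draw_change <- function() {
    up <- runif(1) >= config$downlist_prob
    from <- sample1(scale, NULL)
    to <- if (up) {
      if (from == "CR") "EW" else scale[match(from, scale) + 1]
    } else {
      if (from == "VU") "NT" else scale[match(from, scale) - 1]
    }
    list(from = from, to = to, up = up)
  }
  for (id in taxon_ids) {
    u <- runif(1)
    y1 <- sample(2006:2015, 1)
    ch <- draw_change()
    if (u < config$reversal_prob) {
      # genuine change later reversed by a non-genuine one: both dropped
      recs[[length(recs) + 1]] <- mk(id, y1, ch$from, ch$to, "genuine")
      recs[[length(recs) + 1]] <- mk(id, y1 + sample(1:5, 1), ch$to, ch$from,
                                     "nongenuine")
    } else if (u < config$reversal_prob + config$nongenuine_prob) {
      recs[[length(recs) + 1]] <- mk(id, y1, ch$from, ch$to, "nongenuine")
    } else if (u < config$reversal_prob + config$nongenuine_prob +
               config$multi_prob) {
      # two genuine changes in the same direction: first survives
      first <- mk(id, y1, ch$from, ch$to, "genuine")
      recs[[length(recs) + 1]] <- first
      if (ch$to %in% scale) {
        ch2 <- if (ch$up && ch$to != "CR")
          list(from = ch$to, to = scale[match(ch$to, scale) + 1])
        else if (!ch$up && ch$to != "VU")
          list(from = ch$to, to = scale[match(ch$to, scale) - 1])
        else NULL
        if (!is.null(ch2))
          recs[[length(recs) + 1]] <- mk(id, y1 + sample(1:4, 1),
                                         ch2$from, ch2$to, "genuine")
      }
      exp_rows[[length(exp_rows) + 1]] <-
        dplyr::mutate(first,
                      direction = if (ch$up) "uplisted" else "downlisted")
    } else {
      rec <- mk(id, y1, ch$from, ch$to, "genuine")
      recs[[length(recs) + 1]] <- rec
      exp_rows[[length(exp_rows) + 1]] <-
        dplyr::mutate(rec,
                      direction = if (ch$up) "uplisted" else "downlisted")
    }
  }
  records <- dplyr::bind_rows(recs)
  records <- records[sample(nrow(records)), , drop = FALSE]
  expected <- if (length(exp_rows)) dplyr::bind_rows(exp_rows)
    else tibble::tibble(taxon_id = character(0), year = integer(0),
                        from_category = character(0),
                        to_category = character(0), reason = character(0),
                        note = character(0), direction = character(0))
  list(records = records, expected = expected)
}
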