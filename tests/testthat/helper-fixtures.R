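# Shared fixtures: tiny landscapes and tables built in code.

# a flat 4x4 world: one habitat class fully covering every cell, flat DEM
flat_stack <- function(nx = 4, ny = 4, cell_km = 1, elev = 100) {
  grid <- cg_grid(nx, ny, cell_km)
  cg_stack(grid,
           layers = list("1.1" = matrix(1, nx, ny)),
           dem = matrix(elev, nx, ny))
}

# random rectangles inside [0, w] x [0, h]
random_rects <- function(n, w, h) {
  x0 <- runif(n, 0, w * 0.9); y0 <- runif(n, 0, h * 0.9)
  cg_rects(xmin = x0, ymin = y0,
           xmax = x0 + runif(n, 0.05, w - x0),
           ymax = y0 + runif(n, 0.05, h - y0))
}

# brute-force AOH + PA overlap oracle: naive per-cell loop applying the
# three masks (range membership, habitat fraction, elevation window),
# entirely independent of the package's vectorized path
brute_force_aoh <- function(rects, habitat_layers, suitable_codes, dem,
                            emin, emax, pa_cov, cell_km) {
  nx <- nrow(dem); ny <- ncol(dem)
  aoh_sum <- 0; inter <- 0
  for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
    cx <- (ix - 0.5) * cell_km; cy <- (iy - 0.5) * cell_km
    inside <- FALSE
    for (k in seq_len(nrow(rects))) {
      if (cx >= rects$xmin[k] && cx < rects$xmax[k] &&
          cy >= rects$ymin[k] && cy < rects$ymax[k]) { inside <- TRUE; break }
    }
    if (!inside) next
    f <- 0
    for (cd in suitable_codes) f <- f + habitat_layers[[cd]][ix, iy]
    f <- min(f, 1)
    e <- dem[ix, iy]
    if (!is.na(emin) && e < emin) f <- 0
    if (!is.na(emax) && e > emax) f <- 0
    aoh_sum <- aoh_sum + f
    inter <- inter + f * pa_cov[ix, iy]
  }
  list(area = aoh_sum * cell_km^2,
       overlap_pct = if (aoh_sum > 0) 100 * inter / aoh_sum else NA_real_)
}

# minimal all-FALSE evidence row(s)
empty_evidence <- function(ids) {
  ev <- tibble::tibble(taxon_id = ids)
  for (cat in intervention_categories()) {
    ev[[paste0(cat, "_tabular")]] <- FALSE
    ev[[paste0(cat, "_text")]] <- FALSE
  }
  ev
}

with_flag <- function(ev, id, col, value = TRUE) {
  ev[[col]][ev$taxon_id == id] <- value
  ev
}
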