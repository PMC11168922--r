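test_that("representation threshold hits its anchors and interpolates", {
  expect_equal(representation_threshold(5e3), 100)
  expect_equal(representation_threshold(1e4), 100)
  expect_equal(representation_threshold(2.5e5), 15)
  expect_equal(representation_threshold(3e5), 15)
  # independent oracle: two-point interpolation in log10 area
  oracle <- stats::approx(x = log10(c(1e4, 2.5e5)), y = c(100, 15),
                          xout = log10(5e4), rule = 2)$y
  mid <- representation_threshold(5e4)
  expect_gt(mid, 15); expect_lt(mid, 100)
  expect_equal(mid, oracle, tolerance = 1e-12)
  expect_error(representation_threshold(-1), "nonnegative")
})

test_that("threshold curve is continuous and non-increasing", {
  areas <- 10^seq(2, 6.5, length.out = 1000)
  v <- representation_threshold(areas)
  expect_true(all(diff(v) <= 1e-12))
  expect_true(all(v >= 15 & v <= 100))
  expect_lt(max(abs(diff(v))), 1) # no jumps on a fine grid
})

test_that("species protection score matches the worked examples", {
  expect_equal(species_protection_score(50, 80), 62.5)
  expect_equal(species_protection_score(50, 50), 100)
  expect_equal(species_protection_score(0, 40), 0)
  expect_equal(species_protection_score(90, 30), 100) # capped
  expect_error(species_protection_score(50, 0), "threshold_pct")
  expect_error(species_protection_score(101, 50), "overlap_pct")
})

test_that("sps is monotone in overlap and threshold and stays in [0,100]", {
  set.seed(5)
  ov <- sort(runif(50, 0, 100)); th <- sort(runif(50, 1, 100))
  s_ov <- species_protection_score(ov, 50)
  expect_true(all(diff(s_ov) >= 0))
  s_th <- species_protection_score(50, th)
  expect_true(all(diff(s_th) <= 0))
  expect_true(all(s_ov >= 0 & s_ov <= 100 & s_th >= 0 & s_th <= 100))
})

test_that("AOH equals cell arithmetic when masks are trivial", {
  st <- flat_stack(4, 4, cell_km = 1, elev = 100)
  rect <- cg_rects(0, 0, 2, 2) # covers cells (1,1),(1,2),(2,1),(2,2)
  res <- compute_aoh(rect, "1.1", NA, NA, st)
  expect_equal(res$area_km2, 4)
  # elevation gradient excludes half the cells
  dem <- matrix(100, 4, 4); dem[1, ] <- 500
  st2 <- cg_stack(st$grid, st$layers, dem)
  res2 <- compute_aoh(rect, "1.1", NA, 200, st2)
  expect_equal(res2$area_km2, 2)
  # empty range is area zero, not an error
  expect_equal(compute_aoh(rect[0, ], "1.1", NA, NA, st)$area_km2, 0)
})

test_that("level-1 habitat codes expand to nested level-2 classes", {
  grid <- cg_grid(2, 2, 1)
  st <- cg_stack(grid,
                 layers = list("1.1" = matrix(0.5, 2, 2),
                               "1.2" = matrix(0.25, 2, 2),
                               "2.1" = matrix(0.25, 2, 2)),
                 dem = matrix(0, 2, 2))
  rect <- cg_rects(0, 0, 2, 2)
  expect_equal(compute_aoh(rect, "1", NA, NA, st)$area_km2, 4 * 0.75)
  expect_equal(compute_aoh(rect, "1.1", NA, NA, st)$area_km2, 4 * 0.5)
  # no preference: all classes suitable (fractions sum to 1)
  expect_equal(compute_aoh(rect, character(0), NA, NA, st)$area_km2, 4)
})

test_that("PA overlap reproduces trivial saturation and emptiness", {
  aoh <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(pa_overlap_fraction(aoh, matrix(1, 2, 2)), 100)
  expect_equal(pa_overlap_fraction(aoh, matrix(0, 2, 2)), 0)
  expect_true(is.na(pa_overlap_fraction(matrix(0, 2, 2), matrix(1, 2, 2))))
})

test_that("raster pipeline equals brute-force enumeration on random worlds", {
  set.seed(99)
  for (rep in 1:30) {
    nx <- 20; ny <- 20; cell <- 1
    grid <- cg_grid(nx, ny, cell)
    layers <- list("1.1" = matrix(runif(nx * ny), nx, ny),
                   "1.2" = matrix(runif(nx * ny, 0, 0.5), nx, ny))
    dem <- matrix(runif(nx * ny, 0, 1000), nx, ny)
    st <- cg_stack(grid, layers, dem)
    rects <- random_rects(sample(1:3, 1), nx, ny)
    pa <- random_rects(sample(1:4, 1), nx, ny)
    pa_cov <- coverage_fraction(pa, grid)
    emin <- if (runif(1) < 0.5) runif(1, 0, 400) else NA
    emax <- if (runif(1) < 0.5) runif(1, 500, 1000) else NA
    codes <- sample(c("1.1", "1.2"), sample(1:2, 1))
    res <- compute_aoh(rects, codes, emin, emax, st)
    ov <- pa_overlap_fraction(res$aoh, pa_cov)
    oracle <- brute_force_aoh(rects, layers, codes, dem, emin, emax,
                              pa_cov, cell)
    expect_equal(res$area_km2, oracle$area, tolerance = 1e-9)
    if (!is.na(oracle$overlap_pct))
      expect_equal(ov, oracle$overlap_pct, tolerance = 1e-9)
  }
})

test_that("AOH never exceeds the rasterized range area", {
  set.seed(21)
  st <- flat_stack(10, 10)
  for (rep in 1:20) {
    rects <- random_rects(2, 10, 10)
    n_cells <- sum(cells_in_rects(rects, st$grid))
    res <- compute_aoh(rects, "1.1", NA, NA, st)
    expect_lte(res$area_km2, n_cells * cell_area_km2(st$grid) + 1e-12)
  }
})

test_that("zero-AOH fallback applies the 5-year window and 300 m buffer", {
  pa <- cg_rects(xmin = 1, ymin = 1, xmax = 2, ymax = 2)
  pt <- function(x, y, yr) tibble::tibble(taxon_id = "a", x = x, y = y,
                                          year = yr)
  expect_true(zero_aoh_fallback(pt(1.5, 1.5, 2018), pa, 2020))
  expect_false(zero_aoh_fallback(pt(1.5, 1.5, 2013), pa, 2020)) # stale
  # 250 m outside the boundary: buffer reaches; 400 m: it does not
  expect_true(zero_aoh_fallback(pt(0.75, 1.5, 2019), pa, 2020))
  expect_false(zero_aoh_fallback(pt(0.6, 1.5, 2019), pa, 2020))
  expect_false(zero_aoh_fallback(pt(1.5, 1.5, 2018)[0, ], pa, 2020))
})

test_that("meaningful protection uses the either-basis rule", {
  st <- flat_stack(4, 4)
  pa_all <- cg_rects(0, 0, 4, 4)
  pa_cov <- coverage_fraction(pa_all, st$grid)
  rect <- cg_rects(0, 0, 2, 2)
  res <- meaningful_protection(rect, "1.1", NA, NA, st, pa_cov, pa_all)
  expect_true(res$meaningful)
  expect_equal(res$sps, 100)
  expect_equal(res$basis, "either")
  # no PA at all: both scores fall short
  pa_none <- pa_all[0, ]
  res2 <- meaningful_protection(rect, "1.1", NA, NA, st,
                                coverage_fraction(pa_none, st$grid), pa_none)
  expect_false(res2$meaningful)
  # unsuitable habitat zeroes the AOH and the expert score falls short of
  # its target; a recent in-PA occurrence point rescues the species
  st0 <- cg_stack(st$grid, list("1.1" = matrix(0, 4, 4)), st$dem)
  pa_small <- cg_rects(3, 3, 4, 4)
  cov_small <- coverage_fraction(pa_small, st$grid)
  pts <- tibble::tibble(taxon_id = "a", x = 3.5, y = 3.5, year = 2019)
  res3 <- meaningful_protection(rect, "1.1", NA, NA, st0, cov_small,
                                pa_small, points = pts,
                                reference_year = 2020)
  expect_true(res3$meaningful)
  expect_equal(res3$basis, "point_fallback")
  # same but the only point is stale: not meaningful
  pts_old <- tibble::tibble(taxon_id = "a", x = 3.5, y = 3.5, year = 2010)
  res4 <- meaningful_protection(rect, "1.1", NA, NA, st0, cov_small,
                                pa_small, points = pts_old,
                                reference_year = 2020)
  expect_false(res4$meaningful)
  expect_error(meaningful_protection(rect[0, ], "1.1", NA, NA, st, pa_cov,
                                     pa_all),
               "no range data")
})

test_that("expanding the PA layer never decreases overlap or meaningful", {
  set.seed(31)
  st <- flat_stack(10, 10)
  rect <- cg_rects(1, 1, 8, 8)
  pa1 <- random_rects(2, 10, 10)
  extra <- random_rects(2, 10, 10)
  pa2 <- dplyr::bind_rows(pa1, extra)
  for (pair in 1:10) {
    pa1 <- random_rects(2, 10, 10)
    pa2 <- dplyr::bind_rows(pa1, random_rects(2, 10, 10))
    r1 <- meaningful_protection(rect, "1.1", NA, NA, st,
                                coverage_fraction(pa1, st$grid), pa1)
    r2 <- meaningful_protection(rect, "1.1", NA, NA, st,
                                coverage_fraction(pa2, st$grid), pa2)
    expect_gte(r2$overlap_pct + 1e-9, r1$overlap_pct)
    expect_true(!r1$meaningful || r2$meaningful)
  }
})
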