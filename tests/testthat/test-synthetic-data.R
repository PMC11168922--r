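test_that("invalid configs are rejected with the offending fields named", {
  expect_error(synthetic_world_config(neglect_prob = 1.4), "neglect_prob")
  expect_error(synthetic_world_config(range_km2 = c(10, 5)), "range_km2")
  expect_error(synthetic_world_config(class_probs = c(A = 0.5, B = 0.2)),
               "class_probs")
  expect_error(synthetic_world_config(n_species = 0), "n_species")
})

test_that("generation is fully determined by the seed", {
  cfg <- synthetic_world_config(n_species = 30)
  w1 <- generate_world(cfg, seed = 11)
  w2 <- generate_world(cfg, seed = 11)
  expect_identical(w1$tables, w2$tables)
  expect_identical(w1$ground_truth, w2$ground_truth)
  expect_identical(w1$stack$dem, w2$stack$dem)
  w3 <- generate_world(cfg, seed = 12)
  expect_false(identical(w1$tables$species, w3$tables$species))
  # byte-identical on disk
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_world(w1, d1); write_world(w2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("full PA coverage saturates every positive-AOH species", {
  cfg <- synthetic_world_config(n_species = 40, pa_coverage = 1,
                                neglect_prob = 0)
  w <- generate_world(cfg, seed = 4)
  prot <- protection_table(w$tables$species, w$tables$ranges, w$stack,
                           w$tables$pas, w$tables$points,
                           reference_year = cfg$reference_year)
  pos <- prot$aoh_area_km2 > 0
  expect_true(any(pos))
  expect_equal(prot$overlap_pct[pos], rep(100, sum(pos)), tolerance = 1e-9)
  expect_true(all(prot$sps[pos] == 100))
  expect_true(all(prot$meaningful[pos]))
})

test_that("generated bundles round-trip through the package readers", {
  cfg <- synthetic_world_config(n_species = 25)
  w <- generate_world(cfg, seed = 6)
  d <- file.path(tempdir(), "roundtrip")
  write_world(w, d)
  back <- read_world(d)
  expect_equal(back$tables$species$taxon_id, w$tables$species$taxon_id)
  expect_equal(back$tables$threats$code, w$tables$threats$code)
  expect_equal(back$tables$ranges$xmin, w$tables$ranges$xmin)
  expect_equal(back$stack$dem, w$stack$dem, tolerance = 1e-12)
  expect_equal(names(back$stack$layers), names(w$stack$layers))
  expect_equal(back$grid$cell_km, w$grid$cell_km)
  expect_equal(back$ground_truth$neglected, w$ground_truth$neglected)
})

test_that("planted labels rule the evidence tables by construction", {
  cfg <- synthetic_world_config(n_species = 80)
  w <- generate_world(cfg, seed = 8)
  gt <- w$ground_truth
  ev <- w$tables$evidence
  idx <- match(gt$taxon_id, ev$taxon_id)
  flag_cols <- setdiff(names(ev), "taxon_id")
  any_flag <- rowSums(as.matrix(ev[idx, flag_cols])) > 0
  # neglected species carry no evidence flags at all
  expect_false(any(any_flag[gt$neglected]))
  # and no qualifying listing rows
  expect_false(any(w$tables$listings$group %in% gt$taxon_id[gt$neglected]))
})

test_that("status-change generation plants reversals and multi-changes", {
  cfg <- synthetic_world_config(n_status_changes = 200, reversal_prob = 0.2,
                                multi_prob = 0.2)
  sc <- generate_status_changes(cfg, seed = 21)
  # at least one taxon with a genuine+nongenuine reversal pair
  by_taxon <- split(sc$records, sc$records$taxon_id)
  has_rev <- any(vapply(by_taxon, function(d) {
    nrow(d) == 2 && any(d$reason == "genuine") && any(d$reason == "nongenuine")
  }, logical(1)))
  has_multi <- any(vapply(by_taxon, function(d) {
    sum(d$reason == "genuine") >= 2
  }, logical(1)))
  expect_true(has_rev)
  expect_true(has_multi)
  # zero nongenuine rate with no reversals: filter is the identity
  cfg0 <- synthetic_world_config(n_status_changes = 40, nongenuine_prob = 0,
                                 reversal_prob = 0, multi_prob = 0)
  sc0 <- generate_status_changes(cfg0, seed = 22)
  expect_equal(nrow(filter_genuine(sc0$records)), nrow(sc0$records))
})
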