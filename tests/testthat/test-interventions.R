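test_that("evidence cascade is the OR of its three sources", {
  expect_true(cascade_in_place(TRUE, FALSE, FALSE))
  expect_true(cascade_in_place(FALSE, TRUE, FALSE))
  expect_true(cascade_in_place(FALSE, FALSE, TRUE))
  expect_false(cascade_in_place(FALSE, FALSE, FALSE))
})

test_that("trade control accepts CITES listings up the taxonomy", {
  ev <- empty_evidence("sp1")
  tax <- tibble::tibble(taxon_id = "sp1", genus = "Panthera",
                        family = "Felidae")
  cites_genus <- tibble::tibble(group = "Panthera",
                                instrument = "CITES_appendix",
                                instrument_detail = "II")
  expect_true(trade_control_in_place("sp1", ev, cites_genus, tax))
  # tabular flag alone suffices
  ev2 <- with_flag(ev, "sp1", "trade_control_tabular")
  expect_true(trade_control_in_place("sp1", ev2, NULL, NULL))
  # CMS listing is not trade control
  cms <- tibble::tibble(group = "sp1", instrument = "CMS",
                        instrument_detail = "Appendix I")
  expect_false(trade_control_in_place("sp1", ev, cms, tax))
  # no taxonomy row: no inherited listing
  expect_false(trade_control_in_place("sp1", ev, cites_genus,
                                      tax[0, , drop = FALSE]))
})

test_that("legislation is a superset of trade control", {
  ev <- empty_evidence("sp1")
  tax <- tibble::tibble(taxon_id = "sp1", genus = "G", family = "F")
  cms <- tibble::tibble(group = "sp1", instrument = "CMS",
                        instrument_detail = "Appendix I")
  expect_true(legislation_in_place("sp1", ev, cms, tax))
  named <- tibble::tibble(group = "sp1", instrument = "named_agreement",
                          instrument_detail = "Bern Convention")
  expect_true(legislation_in_place("sp1", ev, named, tax))
  unrecognized <- tibble::tibble(group = "sp1",
                                 instrument = "named_agreement",
                                 instrument_detail = "Pact of Nowhere")
  expect_false(legislation_in_place("sp1", ev, unrecognized, tax))
  expect_false(legislation_in_place("sp1", ev, NULL, tax))
  # pointwise superset over random evidence/listing draws
  set.seed(13)
  for (rep in 1:30) {
    ev_r <- empty_evidence("sp1")
    for (col in names(ev_r)[-1]) ev_r[[col]] <- runif(1) < 0.3
    lst <- if (runif(1) < 0.5) cms else
      tibble::tibble(group = "sp1", instrument = "CITES_appendix",
                     instrument_detail = "I")
    tr <- trade_control_in_place("sp1", ev_r, lst, tax)
    lg <- legislation_in_place("sp1", ev_r, lst, tax)
    expect_true(!tr || lg)
  }
})

test_that("island test requires strictly more than 95% island overlap", {
  island <- cg_rects(0, 0, 10, 10, island_id = "I1")
  expect_true(is_island_species(cg_rects(1, 1, 3, 3), island))
  # exactly 95%: a 100-km2 range with 95 on the island
  range95 <- cg_rects(xmin = 0, ymin = 0, xmax = 20, ymax = 5)
  island95 <- cg_rects(0, 0, 19, 5, island_id = "I1")
  expect_equal(rect_intersection_area(range95, island95) /
                 rect_union_area(range95), 0.95)
  expect_false(is_island_species(range95, island95))
  # 96% across two islands
  two <- cg_rects(xmin = c(0, 10), ymin = c(0, 0), xmax = c(9.6, 19.6),
                  ymax = c(5, 5), island_id = c("I1", "I2"))
  range2 <- cg_rects(0, 0, 20, 5)
  expect_equal(rect_intersection_area(range2, two) /
                 rect_union_area(range2), 0.96)
  expect_true(is_island_species(range2, two))
  expect_warning(out <- is_island_species(range2[0, ], island),
                 "zero-area")
  expect_false(out)
})

test_that("invasive control needs island status, naming and overlap", {
  ev <- empty_evidence("sp1")
  range <- cg_rects(1, 1, 3, 3)
  islands <- cg_rects(0, 0, 10, 10, island_id = "I1")
  erad <- tibble::tibble(island_id = "I1",
                         invasive_species_name = "Rattus rattus",
                         outcome = "successful", year = 2005)
  expect_true(invasive_control_in_place("sp1", ev, TRUE, range, erad,
                                        islands, "Rattus rattus"))
  # eradicated species not named as a threat
  expect_false(invasive_control_in_place("sp1", ev, TRUE, range, erad,
                                         islands, "Felis catus"))
  # continental species: eradications are irrelevant
  expect_false(invasive_control_in_place("sp1", ev, FALSE, range, erad,
                                         islands, "Rattus rattus"))
  # failed or in-progress eradications never count
  for (oc in c("failed", "in_progress")) {
    er2 <- erad; er2$outcome <- oc
    expect_false(invasive_control_in_place("sp1", ev, TRUE, range, er2,
                                           islands, "Rattus rattus"))
  }
  # non-overlapping island
  er3 <- erad; er3$island_id <- "I2"
  isl2 <- cg_rects(100, 100, 110, 110, island_id = "I2")
  expect_false(invasive_control_in_place("sp1", ev, TRUE, range, er3,
                                         dplyr::bind_rows(islands, isl2),
                                         "Rattus rattus"))
})

test_that("any-documented rule excludes PA occurrence and trade per se", {
  expect_true(any_documented_intervention(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_true(any_documented_intervention(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_false(any_documented_intervention(FALSE, FALSE, FALSE, FALSE, FALSE))
})

test_that("adding evidence never retracts a status; strict implies relaxed", {
  set.seed(17)
  cfg <- synthetic_world_config(n_species = 50)
  w <- generate_world(cfg, seed = 5)
  sp <- w$tables$species
  prot <- protection_table(sp, w$tables$ranges, w$stack, w$tables$pas,
                           w$tables$points,
                           reference_year = cfg$reference_year)
  base_args <- list(sp, w$tables$evidence, prot, w$tables$ranges,
                    islands = w$tables$islands,
                    listings = w$tables$listings,
                    taxonomy = w$tables$taxonomy,
                    eradications = w$tables$eradications)
  strict <- do.call(intervention_status_table, c(base_args, mode = "strict"))
  relaxed <- do.call(intervention_status_table, c(base_args, mode = "relaxed"))
  expect_true(all(!strict$any_documented | relaxed$any_documented))
  # turn on extra evidence: statuses only gain
  ev_more <- w$tables$evidence
  flip <- sample(nrow(ev_more), 10)
  ev_more$legislation_tabular[flip] <- TRUE
  ev_more$invasive_control_text[flip] <- TRUE
  more_args <- base_args; more_args[[2]] <- ev_more
  strict2 <- do.call(intervention_status_table, c(more_args, mode = "strict"))
  for (col in c("trade_control", "invasive_control", "legislation",
                "any_documented")) {
    expect_true(all(!strict[[col]] | strict2[[col]]),
                info = paste("column", col))
  }
  # matched interventions: strict addressed set within relaxed addressed set
  major <- major_cbd_threats(w$tables$threats)
  major <- dplyr::left_join(tibble::tibble(taxon_id = sp$taxon_id), major,
                            by = "taxon_id")
  for (ct in cbd_categories()) major[[ct]][is.na(major[[ct]])] <- FALSE
  ms <- matched_intervention_status(major, strict, mode = "strict")
  mr <- matched_intervention_status(major, relaxed, mode = "relaxed")
  ok <- is.na(ms$habitat_loss_addressed) |
    !ms$habitat_loss_addressed | mr$habitat_loss_addressed
  expect_true(all(ok))
})
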