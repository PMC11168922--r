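test_that("direction follows the ordered category scale", {
  expect_equal(change_direction("VU", "EN"), "uplisted")
  expect_equal(change_direction("EN", "VU"), "downlisted")
  expect_equal(change_direction("CR", "EW"), "uplisted")
  expect_equal(change_direction("NT", "LC"), "downlisted")
  expect_error(change_direction("VU", "DD"), "outside the ordered scale")
})

sc_rec <- function(id, year, from, to, reason) {
  tibble::tibble(taxon_id = id, year = year, from_category = from,
                 to_category = to, reason = reason, note = "")
}

test_that("a genuine change reversed by a non-genuine one is dropped", {
  # the flying-fox pattern: genuine 2008 downlist, non-genuine 2013 uplist
  recs <- dplyr::bind_rows(
    sc_rec("pteropus", 2008, "EN", "VU", "genuine"),
    sc_rec("pteropus", 2013, "VU", "EN", "nongenuine"))
  expect_equal(nrow(filter_genuine(recs)), 0)
  # a non-genuine change in the SAME direction does not invalidate it
  recs2 <- dplyr::bind_rows(
    sc_rec("b", 2008, "EN", "VU", "genuine"),
    sc_rec("b", 2013, "VU", "NT", "nongenuine"))
  out2 <- filter_genuine(recs2)
  expect_equal(out2$year, 2008)
})

test_that("only the first of multiple genuine changes survives", {
  recs <- dplyr::bind_rows(
    sc_rec("a", 2010, "VU", "EN", "genuine"),
    sc_rec("a", 2015, "EN", "CR", "genuine"),
    sc_rec("c", 2012, "CR", "EN", "genuine"))
  out <- filter_genuine(recs)
  expect_equal(nrow(out), 2)
  expect_equal(out$year[out$taxon_id == "a"], 2010)
  expect_equal(out$direction, c("uplisted", "downlisted"))
})

test_that("filter_genuine is idempotent and yields a subset", {
  set.seed(23)
  cfg <- synthetic_world_config(n_status_changes = 50)
  sc <- generate_status_changes(cfg, seed = 9)
  once <- filter_genuine(sc$records)
  expect_true(all(once$taxon_id %in% sc$records$taxon_id))
  expect_lte(nrow(once), nrow(sc$records))
  twice <- filter_genuine(once)
  expect_equal(dplyr::arrange(twice, taxon_id),
               dplyr::arrange(once, taxon_id))
})

test_that("the filter recovers the generator's planted survivor set", {
  cfg <- synthetic_world_config(n_status_changes = 80)
  for (s in c(2, 14)) {
    sc <- generate_status_changes(cfg, seed = s)
    got <- dplyr::arrange(filter_genuine(sc$records), taxon_id)
    want <- dplyr::arrange(sc$expected, taxon_id)
    expect_equal(got$taxon_id, want$taxon_id)
    expect_equal(got$year, want$year)
    expect_equal(got$direction, want$direction)
  }
})

test_that("crosstab counts match direct counting and preserve margins", {
  changes <- dplyr::bind_rows(
    sc_rec("a", 2010, "VU", "EN", "genuine"),
    sc_rec("b", 2011, "EN", "VU", "genuine"),
    sc_rec("c", 2012, "VU", "CR", "genuine"))
  changes <- filter_genuine(changes)
  statuses <- tibble::tibble(taxon_id = c("a", "b"),
                             any_documented = c(TRUE, TRUE))
  expect_warning(tabs <- crosstab_status_changes(changes, statuses),
                 "lack intervention status")
  expect_equal(tabs$n_excluded, 1)
  expect_equal(sum(tabs$any_intervention$n), 2)
  cell <- tabs$any_intervention
  expect_equal(cell$n[cell$direction == "downlisted" & cell$documented], 1)
  expect_equal(cell$n[cell$direction == "uplisted" & cell$documented], 1)
  # empty change list gives an all-zero table
  empty <- crosstab_status_changes(changes[0, ], statuses)
  expect_equal(sum(empty$any_intervention$n), 0)
})

test_that("single-threat crosstab conditions on the matched intervention", {
  changes <- filter_genuine(dplyr::bind_rows(
    sc_rec("a", 2010, "VU", "EN", "genuine"),   # habitat-only, unaddressed
    sc_rec("b", 2011, "EN", "VU", "genuine"),   # trade-only, addressed
    sc_rec("c", 2012, "VU", "EN", "genuine")))  # two threats: excluded
  statuses <- tibble::tibble(taxon_id = c("a", "b", "c"),
                             any_documented = c(FALSE, TRUE, TRUE))
  matched <- tibble::tibble(
    taxon_id = c("a", "b", "c"),
    habitat_loss_major = c(TRUE, FALSE, TRUE),
    habitat_loss_addressed = c(FALSE, NA, TRUE),
    trade_major = c(FALSE, TRUE, TRUE),
    trade_addressed = c(NA, TRUE, FALSE),
    invasive_major = FALSE, invasive_addressed = NA,
    n_major_threats = c(1, 1, 2))
  tabs <- crosstab_status_changes(changes, statuses, matched)
  st <- tabs$single_threat
  expect_equal(st$n[st$threat == "habitat_loss" & !st$addressed &
                      st$direction == "uplisted"], 1)
  expect_equal(st$n[st$threat == "trade" & st$addressed &
                      st$direction == "downlisted"], 1)
  expect_equal(sum(st$n), 2) # the two-threat species contributes nowhere
})
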