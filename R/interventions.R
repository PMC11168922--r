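# Per-species, per-category decisions on whether a conservation
# intervention is documented as in place: the tri-source evidence cascade
# (Red List tabular flag, text-derived flag, external databases) and the
# matched-intervention logic for the three major threats.

#' The six intervention categories
#'
#' In-place conservation interventions tracked per species: occurrence in
#' at least one protected area, international trade control, invasive
#' species control or prevention, successful reintroduction or benign
#' introduction, inclusion in international legislation, and recent
#' education/awareness programmes. Ex situ conservation is deliberately
#' excluded: the focus is on actions reducing extinction risk in the wild.
#'
#' @return character vector of the six category labels.
#' @export
intervention_categories <- function() {
  c("pa_occurrence", "trade_control", "invasive_control",
    "reintroduction", "legislation", "education")
}

#' Evidence cascade for a single intervention category
#'
#' The first test of whether an intervention is in place is the Red List
#' tabular flag; failing that, the text-derived flag; failing both, any
#' external source supplied for that category (CITES listings, eradication
#' records, the meaningful-protection determination). The result is simply
#' the OR of the three, so adding an evidence source can never retract a
#' positive status.
#'
#' @param tabular_flag,text_flag,external logical vectors (recycled).
#' @return logical vector.
#' @export
cascade_in_place <- function(tabular_flag, text_flag, external = FALSE) {
  as.logical(tabular_flag) | as.logical(text_flag) | as.logical(external)
}

#' Recognised multilateral agreements
#'
#' Named agreements that qualify a species as subject to international
#' legislation when its account text cites one. Ships as an editable CSV
#' in the package's `extdata`.
#'
#' @return tibble with columns `agreement`, `notes`.
#' @export
legislation_agreements <- function() {
  path <- system.file("extdata", "legislation_agreements.csv", package = "consgap")
  readr::read_csv(path, show_col_types = FALSE)
}

# Ancestor chain for a species: its own id plus any genus/family/order/
# class values its taxonomy row provides. Listings of larger taxonomic
# groups are matched against this chain; absent taxonomy rows mean no
# inherited listing.
taxon_chain <- function(taxon_id, taxonomy) {
  chain <- as.character(taxon_id)
  if (!is.null(taxonomy)) {
    row <- taxonomy[taxonomy$taxon_id == taxon_id, , drop = FALSE]
    if (nrow(row) >= 1) {
      for (col in intersect(c("genus", "family", "order", "class"), names(taxonomy))) {
        v <- as.character(row[[col]][1])
        if (!is.na(v) && nzchar(v)) chain <- c(chain, v)
      }
    }
  }
  unique(chain)
}

listed_under <- function(taxon_id, listings, taxonomy, instruments) {
  if (is.null(listings) || nrow(listings) == 0) return(FALSE)
  chain <- taxon_chain(taxon_id, taxonomy)
  any(listings$instrument %in% instruments & listings$group %in% chain)
}

#' International trade control
#'
#' A species is subject to international trade control if the Red List
#' records it as such (tabular or text), or if the species — or a larger
#' taxonomic group it belongs to — is listed on any CITES appendix.
#' Listings under CMS or the EU annexes do not count as trade control
#' (they count toward the broader legislation category).
#'
#' @param taxon_id single species identifier.
#' @param evidence evidence table (see [intervention_status_table()]).
#' @param listings listings table: columns `group` (taxon or higher-group
#'   name), `instrument` (`CITES_appendix`, `CMS`, `EU_annex`,
#'   `named_agreement`), `instrument_detail`.
#' @param taxonomy taxonomy table: `taxon_id` plus any of `genus`,
#'   `family`, `order`, `class`.
#' @return single logical.
#' @export
trade_control_in_place <- function(taxon_id, evidence, listings = NULL,
                                   taxonomy = NULL) {
  ev <- evidence_row(evidence, taxon_id)
  cascade_in_place(ev$trade_control_tabular, ev$trade_control_text,
                   listed_under(taxon_id, listings, taxonomy, "CITES_appendix"))
}

#' International legislation
#'
#' A species is covered by international legislation if any of: it
#' qualifies for international trade control (a strict subset of this
#' category); it appears in a Species+-style listings table under CITES,
#' CMS or the EU annexes; or its account text names a recognised
#' multilateral agreement (matched against [legislation_agreements()]).
#' The Red List's own legislation flags (tabular/text) also count via the
#' cascade.
#'
#' @inheritParams trade_control_in_place
#' @param agreements recognised agreement names (character); defaults to
#'   the shipped table.
#' @return single logical.
#' @export
legislation_in_place <- function(taxon_id, evidence, listings = NULL,
                                 taxonomy = NULL,
                                 agreements = legislation_agreements()$agreement) {
  ev <- evidence_row(evidence, taxon_id)
  trade <- trade_control_in_place(taxon_id, evidence, listings, taxonomy)
  splus <- listed_under(taxon_id, listings, taxonomy,
                        c("CITES_appendix", "CMS", "EU_annex"))
  named <- FALSE
  if (!is.null(listings) && nrow(listings) > 0) {
    chain <- taxon_chain(taxon_id, taxonomy)
    named <- any(listings$instrument == "named_agreement" &
                   listings$group %in% chain &
                   listings$instrument_detail %in% agreements)
  }
  cascade_in_place(ev$legislation_tabular, ev$legislation_text,
                   trade || splus || named)
}

#' Island-species test
#'
#' A species counts as an island species when strictly more than 95% of
#' its historical range area (polygons of all presence codes) lies on
#' islands. Exactly 95% does not qualify.
#'
#' @param historical_rects rectangle table of the full historical range.
#' @param island_rects rectangle table of island polygons.
#' @return single logical; zero-area ranges return `FALSE` with a warning.
#' @export
is_island_species <- function(historical_rects, island_rects) {
  total <- rect_union_area(historical_rects)
  if (total == 0) {
    warning("zero-area historical range; island status set to FALSE")
    return(FALSE)
  }
  on_island <- rect_intersection_area(historical_rects, island_rects)
  on_island / total > 0.95
}

#' Invasive species control
#'
#' In place if the Red List cascade says so, or — for island species only
#' — if a successful eradication event removed one of the invasive
#' vertebrates specifically named as threatening this species, from an
#' island that overlaps the species' range. Continental species can only
#' qualify through the cascade, because eradication data are reliable only
#' for islands.
#'
#' @param taxon_id single species identifier.
#' @param evidence evidence table.
#' @param island_status logical from [is_island_species()].
#' @param range_rects rectangles of the species' range (or AOH footprint).
#' @param eradications table: `island_id`, `invasive_species_name`,
#'   `outcome` (`successful`, `failed`, `in_progress`), `year`.
#' @param islands rectangle table with an `island_id` column.
#' @param named_invasives character vector of invasive species named as
#'   threats to this species.
#' @return single logical.
#' @export
invasive_control_in_place <- function(taxon_id, evidence, island_status,
                                      range_rects, eradications = NULL,
                                      islands = NULL,
                                      named_invasives = character(0)) {
  ev <- evidence_row(evidence, taxon_id)
  external <- FALSE
  if (isTRUE(island_status) && !is.null(eradications) && !is.null(islands) &&
      nrow(eradications) > 0 && length(named_invasives) > 0) {
    ok <- eradications[eradications$outcome == "successful" &
                         eradications$invasive_species_name %in% named_invasives,
                       , drop = FALSE]
    for (isl in unique(ok$island_id)) {
      isl_rects <- islands[islands$island_id == isl, , drop = FALSE]
      if (nrow(isl_rects) > 0 &&
          rect_intersection_area(range_rects, isl_rects) > 0) {
        external <- TRUE
        break
      }
    }
  }
  cascade_in_place(ev$invasive_control_tabular, ev$invasive_control_text,
                   external)
}

evidence_row <- function(evidence, taxon_id) {
  i <- match(taxon_id, evidence$taxon_id)
  if (is.na(i))
    stop("no intervention evidence for taxon ", taxon_id, call. = FALSE)
  evidence[i, , drop = FALSE]
}

#' Any documented conservation intervention
#'
#' Whether a species has at least one documented intervention,
#' irrespective of threat: habitat protection OR international legislation
#' (which subsumes trade control) OR invasive control OR reintroduction OR
#' education. Ex situ conservation is excluded. The `habitat_protected`
#' argument is the mode-appropriate habitat criterion: the
#' meaningful-protection determination in strict mode, the Red List PA
#' occurrence flag in relaxed mode.
#'
#' @param habitat_protected,legislation,invasive_control,reintroduction,education
#'   logical vectors (recycled).
#' @return logical vector.
#' @export
any_documented_intervention <- function(habitat_protected, legislation,
                                        invasive_control, reintroduction,
                                        education) {
  as.logical(habitat_protected) | as.logical(legislation) |
    as.logical(invasive_control) | as.logical(reintroduction) |
    as.logical(education)
}

#' Full intervention status per species
#'
#' Runs the cascade plus the external routes for every species, and
#' derives `any_documented` under the requested mode. In strict mode the
#' habitat criterion is the meaningful-protection determination; relaxed
#' mode only asks whether the species is recorded as occurring in at least
#' one PA (the Red List cascade flag).
#'
#' @param species species table; must carry `taxon_id` and
#'   `named_invasives` (semicolon-separated names, may be empty).
#' @param evidence evidence table: `taxon_id` plus, for each category in
#'   [intervention_categories()], `<category>_tabular` and
#'   `<category>_text` logical columns.
#' @param protection protection results from [protection_table()]
#'   (`taxon_id`, `meaningful`, ...).
#' @param ranges range rectangle table with `presence` codes.
#' @param islands island rectangle table (`island_id` column).
#' @param listings,taxonomy,eradications see the per-category deciders.
#' @param mode `"strict"` or `"relaxed"`.
#' @return tibble: `taxon_id`, the six category logicals,
#'   `island_species`, `meaningful_habitat_protection`, `any_documented`.
#' @export
intervention_status_table <- function(species, evidence, protection, ranges,
                                      islands = NULL, listings = NULL,
                                      taxonomy = NULL, eradications = NULL,
                                      mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  n <- nrow(species)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- species$taxon_id[i]
    ev <- evidence_row(evidence, id)
    rr_all <- ranges[ranges$taxon_id == id, , drop = FALSE]
    rr_cur <- rr_all[rr_all$presence %in% current_presence_codes(), , drop = FALSE]
    island <- if (!is.null(islands) && nrow(rr_all) > 0)
      suppressWarnings(is_island_species(rr_all, islands)) else FALSE
    named_inv <- split_codes(species$named_invasives[i])[[1]]
    pa_occ <- cascade_in_place(ev$pa_occurrence_tabular, ev$pa_occurrence_text)
    trade <- trade_control_in_place(id, evidence, listings, taxonomy)
    invasive <- invasive_control_in_place(id, evidence, island, rr_cur,
                                          eradications, islands, named_inv)
    reintro <- cascade_in_place(ev$reintroduction_tabular, ev$reintroduction_text)
    legis <- legislation_in_place(id, evidence, listings, taxonomy)
    educ <- cascade_in_place(ev$education_tabular, ev$education_text)
    j <- match(id, protection$taxon_id)
    meaningful <- if (!is.na(j)) isTRUE(protection$meaningful[j]) else FALSE
    # relaxed mode *adds* mere PA occurrence to the criterion, so the
    # relaxed documented set always contains the strict one
    habitat_flag <- if (mode == "strict") meaningful else (meaningful | pa_occ)
    rows[[i]] <- tibble::tibble(
      taxon_id = id, pa_occurrence = pa_occ, trade_control = trade,
      invasive_control = invasive, reintroduction = reintro,
      legislation = legis, education = educ, island_species = island,
      meaningful_habitat_protection = meaningful,
      any_documented = any_documented_intervention(habitat_flag, legis,
                                                   invasive, reintro, educ))
  }
  dplyr::bind_rows(rows)
}

#' Matched intervention status for the three major threats
#'
#' For each species and each of its major threats among habitat loss,
#' overexploitation for international trade and invasive species, reports
#' whether the clearly matched intervention is documented: meaningful
#' habitat protection (strict mode) or mere PA occurrence (relaxed mode)
#' for habitat loss; international trade control for trade; invasive
#' species control for invasives.
#'
#' @param major tibble from [major_cbd_threats()].
#' @param statuses tibble from [intervention_status_table()].
#' @param mode `"strict"` or `"relaxed"`.
#' @return tibble: `taxon_id`, per threat a `<threat>_major` logical and a
#'   `<threat>_addressed` logical (`NA` when the threat is not major for
#'   that species), and `n_major_threats` counting the three assessed
#'   threats only.
#' @export
matched_intervention_status <- function(major, statuses,
                                        mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  idx <- match(major$taxon_id, statuses$taxon_id)
  if (anyNA(idx))
    stop("missing intervention status for taxa: ",
         paste(head(major$taxon_id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  st <- statuses[idx, , drop = FALSE]
  habitat_flag <- if (mode == "strict")
    st$meaningful_habitat_protection
  else st$meaningful_habitat_protection | st$pa_occurrence
  hab_major <- major$habitat_loss
  trade_major <- major$overexploitation_international_trade
  inv_major <- major$invasive_species
  tibble::tibble(
    taxon_id = major$taxon_id,
    habitat_loss_major = hab_major,
    habitat_loss_addressed = ifelse(hab_major, habitat_flag, NA),
    trade_major = trade_major,
    trade_addressed = ifelse(trade_major, st$trade_control, NA),
    invasive_major = inv_major,
    invasive_addressed = ifelse(inv_major, st$invasive_control, NA),
    n_major_threats = hab_major + trade_major + inv_major)
}
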