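# Red List status-change records: filtering to genuine changes and
# cross-tabulation of uplists/downlists against intervention presence.

redlist_rank <- function(category) {
  scale <- redlist_categories() # LC < NT < VU < EN < CR < EW < EX
  r <- match(category, scale)
  if (anyNA(r))
    stop("Red List category outside the ordered scale: ",
         paste(unique(category[is.na(r)]), collapse = ", "), call. = FALSE)
  r
}

#' Direction of a Red List status change
#'
#' Uplisted means moved to a higher threat category on the ordered scale
#' LC < NT < VU < EN < CR < EW < EX; any move down the scale is a
#' downlist. EW and EX sit above CR so changes into and out of the
#' extinct categories classify cleanly.
#'
#' @param from,to character vectors of Red List categories.
#' @return character vector: `"uplisted"` or `"downlisted"`.
#' @export
change_direction <- function(from, to) {
  rf <- redlist_rank(from); rt <- redlist_rank(to)
  if (any(rf == rt)) stop("status change with identical categories", call. = FALSE)
  ifelse(rt > rf, "uplisted", "downlisted")
}

#' Filter status-change records to genuine changes
#'
#' Keeps changes that reflect a real change in extinction risk, dropping
#' three things: records flagged non-genuine (new information, taxonomic
#' revision); any genuine change later superseded by a non-genuine change
#' in the opposing direction for the same taxon (an apparent improvement
#' that was really a data correction — in that case both records go); and,
#' for taxa with several surviving genuine changes, everything after the
#' first. Supersession is judged on direction, not on exact category
#' pairs. Idempotent; the output is always a subset of the input.
#'
#' @param records tibble: `taxon_id`, `year`, `from_category`,
#'   `to_category`, `reason` (`"genuine"`/`"nongenuine"`), optional `note`.
#' @return the filtered tibble, with a `direction` column added.
#' @export
filter_genuine <- function(records) {
  stopifnot(all(c("taxon_id", "year", "from_category", "to_category",
                  "reason") %in% names(records)))
  if (nrow(records) == 0) {
    out <- records
    out$direction <- character(0)
    return(out)
  }
  records <- records[order(records$taxon_id, records$year), , drop = FALSE]
  records$direction <- change_direction(records$from_category,
                                        records$to_category)
  keep <- logical(nrow(records))
  for (id in unique(records$taxon_id)) {
    i <- which(records$taxon_id == id)
    genuine <- records$reason[i] == "genuine"
    superseded <- logical(length(i))
    for (k in seq_along(i)) {
      if (!genuine[k]) next
      later <- i[records$year[i] > records$year[i[k]]]
      opp <- setdiff(c("uplisted", "downlisted"), records$direction[i[k]])
      superseded[k] <- any(records$reason[later] == "nongenuine" &
                             records$direction[later] == opp)
    }
    surviving <- i[genuine & !superseded]
    if (length(surviving) > 0) keep[surviving[1]] <- TRUE # first instance only
  }
  records[keep, , drop = FALSE]
}

#' Cross-tabulate status changes against intervention presence
#'
#' Two contingency tables over the surviving genuine changes: (a) counts
#' of uplisted/downlisted species by whether any conservation intervention
#' is documented; (b) for species whose only major threat among the three
#' assessed (habitat loss, international trade, invasive species) is a
#' given threat, counts by whether that threat's matched intervention is
#' in place.
#'
#' @param changes filtered status changes (from [filter_genuine()]).
#' @param statuses intervention statuses (from
#'   [intervention_status_table()]); species missing from it are excluded
#'   with a warning count.
#' @param matched matched-intervention table (from
#'   [matched_intervention_status()]); used for table (b).
#' @return list with `any_intervention` (tibble: `direction`,
#'   `documented`, `n`), `single_threat` (tibble: `threat`, `addressed`,
#'   `direction`, `n`) and `n_excluded`.
#' @export
crosstab_status_changes <- function(changes, statuses, matched = NULL) {
  dirs <- c("downlisted", "uplisted")
  grid_a <- expand.grid(direction = dirs, documented = c(FALSE, TRUE),
                        stringsAsFactors = FALSE)
  grid_a$n <- 0L
  excluded <- 0L
  if (nrow(changes) > 0) {
    idx <- match(changes$taxon_id, statuses$taxon_id)
    excluded <- sum(is.na(idx))
    if (excluded > 0)
      warning(excluded, " changed species lack intervention status; excluded")
    ok <- !is.na(idx)
    doc <- statuses$any_documented[idx[ok]]
    dir <- changes$direction[ok]
    for (r in seq_len(nrow(grid_a))) {
      grid_a$n[r] <- sum(dir == grid_a$direction[r] & doc == grid_a$documented[r])
    }
  }
  out <- list(any_intervention = tibble::as_tibble(grid_a),
              n_excluded = excluded)

  if (!is.null(matched)) {
    threats <- c(habitat_loss = "habitat_loss", trade = "trade",
                 invasive = "invasive")
    rows <- list()
    midx <- match(changes$taxon_id, matched$taxon_id)
    for (th in names(threats)) {
      maj_col <- paste0(th, "_major")
      if (th == "habitat_loss") maj_col <- "habitat_loss_major"
      addr_col <- sub("_major$", "_addressed", maj_col)
      for (addressed in c(TRUE, FALSE)) for (dir in dirs) {
        cnt <- 0L
        for (k in seq_len(nrow(changes))) {
          m <- midx[k]
          if (is.na(m)) next
          only_this <- isTRUE(matched[[maj_col]][m]) &&
            matched$n_major_threats[m] == 1
          if (only_this && isTRUE(matched[[addr_col]][m] == addressed) &&
              changes$direction[k] == dir)
            cnt <- cnt + 1L
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          threat = th, addressed = addressed, direction = dir, n = cnt)
      }
    }
    out$single_threat <- dplyr::bind_rows(rows)
  }
  out
}
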