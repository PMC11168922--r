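# Taxon/country aggregation and binomial GLM inference with
# likelihood-ratio tests by single-term deletion.

#' Summarize apparent neglect by country
#'
#' Counts, per country (optionally per taxonomic class), the species
#' lacking versus having a given attribute (typically "lacks the matched
#' intervention" or "lacks any documented intervention"). Interventions
#' are not spatially explicit, so in map mode a non-endemic species
#' contributes to every country of its distribution; endemic mode keeps
#' only single-country species, which pinpoints where effort is lacking at
#' the cost of coverage.
#'
#' @param species species table with `taxon_id`, `countries`
#'   (semicolon-separated country codes), `endemic_country` (code or empty)
#'   and `taxon_class`.
#' @param lacking logical vector aligned with `species` rows: does this
#'   species lack the intervention under study?
#' @param endemics_only restrict to country endemics?
#' @param by_class additionally group by `taxon_class`?
#' @return tibble: `country` (, `taxon_class`), `n_lacking`, `n_having`,
#'   `n_total` with `n_lacking + n_having = n_total` in every row.
#' @export
summarize_by_country <- function(species, lacking, endemics_only = FALSE,
                                 by_class = FALSE) {
  stopifnot(length(lacking) == nrow(species))
  rows <- list()
  for (i in seq_len(nrow(species))) {
    ctys <- split_codes(species$countries[i])[[1]]
    if (endemics_only) {
      e <- species$endemic_country[i]
      if (is.na(e) || !nzchar(e) || length(ctys) != 1) next
      ctys <- e
    }
    if (length(ctys) == 0) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      country = ctys,
      taxon_class = species$taxon_class[i],
      lacking = lacking[i])
  }
  if (length(rows) == 0) {
    out <- tibble::tibble(country = character(0), n_lacking = integer(0),
                          n_having = integer(0), n_total = integer(0))
    if (by_class) out <- tibble::add_column(out, taxon_class = character(0),
                                            .after = "country")
    return(out)
  }
  long <- dplyr::bind_rows(rows)
  keys <- if (by_class) c("country", "taxon_class") else "country"
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n_lacking = sum(lacking), n_having = sum(!lacking),
                     n_total = dplyr::n(), .groups = "drop")
}

#' Fit a binomial GLM on grouped proportions
#'
#' Maximum-likelihood logistic fit of grouped successes/failures against
#' arbitrary terms (taxonomic class, Red List category and their
#' interaction, country, log GDP, endemic counts, evolutionary
#' distinctiveness, ...). A thin, validated wrapper around the standard
#' iteratively reweighted least-squares fit; non-convergence and
#' (quasi-)complete separation are surfaced as diagnostics on the returned
#' object instead of silent warnings.
#'
#' @param data data frame with integer columns `successes` and `trials`
#'   (`trials >= successes >= 0`) plus the covariates named in `formula`.
#' @param formula right-hand side terms, e.g. `~ class * category`.
#' @return object of class `cg_glm`: list with the underlying `glm` fit
#'   (`$fit`), `$deviance`, `$df_residual`, `$converged` and
#'   `$separation` (logical diagnostic).
#' @export
fit_binomial_glm <- function(data, formula) {
  stopifnot(all(c("successes", "trials") %in% names(data)))
  if (any(data$successes < 0 | data$trials < data$successes))
    stop("need trials >= successes >= 0 in every group", call. = FALSE)
  data$failures <- data$trials - data$successes
  f <- stats::update(formula, cbind(successes, failures) ~ .)
  fit <- suppressWarnings(stats::glm(f, family = binomial(), data = data))
  separation <- any(abs(coef(fit)[is.finite(coef(fit))]) > 15)
  structure(list(fit = fit, deviance = fit$deviance,
                 df_residual = fit$df.residual,
                 converged = fit$converged, separation = separation,
                 formula = formula),
            class = "cg_glm")
}

#' @export
print.cg_glm <- function(x, ...) {
  cat("<cg_glm> binomial GLM, deviance", format(x$deviance, digits = 5),
      "on", x$df_residual, "d.f.")
  if (!x$converged) cat("  [DID NOT CONVERGE]")
  if (x$separation) cat("  [possible separation]")
  cat("\n")
  invisible(x)
}

#' Likelihood-ratio tests by single-term deletion
#'
#' Drops each droppable term in turn (respecting marginality: main
#' effects under a retained interaction are not dropped) and compares the
#' reduced model to the full model with a chi-squared likelihood-ratio
#' test.
#'
#' @param fit a `cg_glm` from [fit_binomial_glm()].
#' @return tidy tibble: `term`, `deviance` (change in deviance), `df`,
#'   `p_value`.
#' @export
lrt_drop_each <- function(fit) {
  stopifnot(inherits(fit, "cg_glm"))
  if (!fit$converged)
    warning("full model did not converge; likelihood-ratio tests are suspect")
  d1 <- stats::drop1(fit$fit, test = "Chisq")
  terms <- rownames(d1)[-1]
  tibble::tibble(term = terms,
                 deviance = d1$LRT[-1],
                 df = d1$Df[-1],
                 p_value = d1$`Pr(>Chi)`[-1])
}

#' Standardize evolutionary distinctiveness within classes
#'
#' Rescales ED values to `[0, 1]` within each taxonomic class:
#' `(x - min) / (max - min)` per class, so classes with very different ED
#' scales become comparable. A class with a single distinct value maps to
#' all zeros with a warning.
#'
#' @param ed numeric vector of nonnegative ED values.
#' @param class character vector of class labels, same length.
#' @return numeric vector in `[0, 1]`.
#' @export
standardize_ed <- function(ed, class) {
  stopifnot(length(ed) == length(class))
  if (any(!is.finite(ed)) || any(ed < 0))
    stop("ed must be finite and nonnegative", call. = FALSE)
  out <- numeric(length(ed))
  for (cl in unique(class)) {
    i <- class == cl
    rng <- range(ed[i])
    if (rng[1] == rng[2]) {
      warning("class '", cl, "' has constant ED; standardized to 0")
      out[i] <- 0
    } else {
      out[i] <- (ed[i] - rng[1]) / (rng[2] - rng[1])
    }
  }
  out
}
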