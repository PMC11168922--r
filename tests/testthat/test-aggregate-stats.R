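test_that("country summaries assign non-endemics everywhere, endemics once", {
  sp <- tibble::tibble(
    taxon_id = c("a", "b", "c"),
    taxon_class = c("Aves", "Aves", "Mammalia"),
    countries = c("C01;C02;C03", "C01", ""),
    endemic_country = c(NA, "C01", NA))
  out <- summarize_by_country(sp, lacking = c(TRUE, FALSE, TRUE))
  expect_equal(out$n_lacking[out$country == "C01"], 1)
  expect_equal(out$n_total[out$country == "C01"], 2)
  expect_equal(out$n_lacking[out$country == "C02"], 1)
  expect_true(all(out$n_lacking + out$n_having == out$n_total))
  end <- summarize_by_country(sp, lacking = c(TRUE, FALSE, TRUE),
                              endemics_only = TRUE)
  expect_equal(nrow(end), 1)
  expect_equal(end$country, "C01")
  expect_equal(end$n_total, 1)
})

test_that("planted per-country counts are recovered exactly", {
  set.seed(3)
  n <- 120
  ctys <- sprintf("C%02d", 1:6)
  home <- sample(ctys, n, replace = TRUE)
  lacking <- runif(n) < 0.4
  sp <- tibble::tibble(taxon_id = sprintf("s%03d", 1:n),
                       taxon_class = "Aves",
                       countries = home, endemic_country = home)
  out <- summarize_by_country(sp, lacking)
  for (ct in unique(home)) {
    expect_equal(out$n_lacking[out$country == ct],
                 sum(lacking[home == ct]))
  }
})

test_that("binomial GLM reproduces saturation and null-effect behaviour", {
  # identical proportions in two groups: factor explains ~nothing
  d <- tibble::tibble(successes = c(30, 60), trials = c(100, 200),
                      g = c("a", "b"))
  fit <- fit_binomial_glm(d, ~ g)
  expect_true(fit$converged)
  lrt <- lrt_drop_each(fit)
  expect_lt(lrt$deviance[lrt$term == "g"], 1e-8)
  # saturated model: residual deviance ~ 0
  d2 <- tibble::tibble(successes = c(10, 25, 40), trials = c(50, 50, 50),
                       g = c("a", "b", "c"))
  fit2 <- fit_binomial_glm(d2, ~ g)
  expect_lt(fit2$deviance, 1e-8)
  expect_error(fit_binomial_glm(tibble::tibble(successes = 5, trials = 3),
                                ~ 1), "trials >= successes")
})

test_that("per-country saturated fit reproduces raw proportions", {
  set.seed(8)
  d <- tibble::tibble(country = sprintf("C%02d", 1:10),
                      trials = sample(50:200, 10))
  d$successes <- rbinom(10, d$trials, runif(10, 0.1, 0.9))
  fit <- fit_binomial_glm(d, ~ country)
  p_hat <- fitted(fit$fit)
  expect_equal(unname(p_hat), d$successes / d$trials, tolerance = 1e-8)
})

test_that("planted logit effects are recovered within 3 SE", {
  set.seed(42)
  beta <- 1.0; n_group <- 400
  hits <- 0; reps <- 60
  for (r in 1:reps) {
    x <- rep(c(0, 1), each = 20)
    eta <- -0.5 + beta * x
    d <- tibble::tibble(successes = rbinom(40, n_group, plogis(eta)),
                        trials = n_group, x = x)
    fit <- fit_binomial_glm(d, ~ x)
    est <- coef(fit$fit)["x"]
    se <- sqrt(diag(vcov(fit$fit)))["x"]
    if (abs(est - beta) <= 3 * se) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})

test_that("deviance differences respect nesting and marginality", {
  set.seed(15)
  d <- expand.grid(g = c("a", "b", "c"), h = c("x", "y"),
                   stringsAsFactors = FALSE)
  d$trials <- 100
  d$successes <- rbinom(nrow(d), d$trials, 0.4)
  full <- fit_binomial_glm(d, ~ g * h)
  lrt <- lrt_drop_each(full)
  # only the interaction is droppable under marginality
  expect_equal(lrt$term, "g:h")
  expect_gte(lrt$deviance, -1e-10)
  main <- fit_binomial_glm(d, ~ g + h)
  lrt2 <- lrt_drop_each(main)
  expect_setequal(lrt2$term, c("g", "h"))
  expect_true(all(lrt2$deviance >= -1e-10))
  # adding terms never increases residual deviance
  expect_lte(full$deviance, main$deviance + 1e-10)
})

test_that("ED standardization maps each class onto [0, 1]", {
  ed <- c(2, 4, 6, 10, 30)
  cls <- c("A", "A", "A", "B", "B")
  out <- standardize_ed(ed, cls)
  expect_equal(out, c(0, 0.5, 1, 0, 1))
  expect_warning(z <- standardize_ed(c(5, 5), c("C", "C")), "constant ED")
  expect_equal(z, c(0, 0))
  expect_error(standardize_ed(c(-1, 2), c("A", "A")), "nonnegative")
})
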