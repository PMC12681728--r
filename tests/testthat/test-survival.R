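test_that("Kaplan-Meier cumulative incidence matches hand product-limit results", {
  # no censoring: KM = empirical CDF
  expect_equal(km_cumulative_incidence(c(1, 2, 3, 25), c(1, 1, 1, 0), 20), 0.75)
  expect_equal(km_cumulative_incidence(c(3, 8, 30), c(0, 0, 0), 20), 0)
  # hand product-limit: S(20) = (3/4) * (1/2); follow-up ends before the
  # horizon, so the carry-forward warning fires
  expect_warning(
    inc <- km_cumulative_incidence(c(1, 2, 3, 4), c(1, 0, 1, 0), 20),
    "carrying the last"
  )
  expect_equal(inc, 1 - (3 / 4) * (1 / 2))
  expect_warning(km_cumulative_incidence(c(1, 2), c(1, 0), 20),
                 "carrying the last")
  expect_error(km_cumulative_incidence(c(0, 1), c(1, 1), 20),
               class = "g6pd_invalid_input")
})

test_that("KM equals the empirical CDF complement on censoring-free data", {
  set.seed(13)
  t <- round(rexp(80, 0.08), 2) + 0.01
  for (h in c(5, 10, 20)) {
    expect_equal(
      suppressWarnings(km_cumulative_incidence(t, rep(1, 80), h)),
      mean(t <= h)
    )
  }
})

test_that("the Cox fit matches a brute-force partial-likelihood oracle", {
  time <- c(1.1, 2.3, 3.7, 4.2, 5.9, 7.4, 8.8, 9.5)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  x <- c(1, 0, 1, 0, 1, 0, 1, 0)
  d <- tibble::tibble(time_years = time, event = event, grp = x)
  fit <- cox_fit(d, "grp")
  oracle <- stats::optimize(oracle_cox_loglik(time, event, x),
                            c(-5, 5), maximum = TRUE)
  expect_equal(fit$beta, oracle$maximum, tolerance = 1e-4)
})

test_that("Cox estimates are invariant to dataset replication", {
  d <- make_survival_sample(400, hr = 1.5, seed = 21)
  # exact under Breslow: duplication scales every risk-set sum by 2, a
  # constant offset in the partial log-likelihood
  one <- cox_fit(d, "grp", ties = "breslow")
  two <- cox_fit(dplyr::bind_rows(d, d), "grp", ties = "breslow")
  expect_equal(one$hr, two$hr, tolerance = 1e-8)
  expect_lt(two$conf_high - two$conf_low, one$conf_high - one$conf_low)
  # Efron's fractional tie correction perturbs the doubled fit only slightly
  e1 <- cox_fit(d, "grp", ties = "efron")
  e2 <- cox_fit(dplyr::bind_rows(d, d), "grp", ties = "efron")
  expect_equal(e1$hr, e2$hr, tolerance = 1e-2)
})

test_that("degenerate survival inputs raise classed errors", {
  d <- make_survival_sample(50, hr = 1.4, seed = 3)
  d$flat <- 1
  expect_error(cox_fit(d, "flat"), class = "g6pd_invalid_input")
  d2 <- d
  d2$event <- FALSE
  expect_error(cox_fit(d2, "grp"), class = "g6pd_invalid_input")
})

test_that("a planted hazard ratio of 1.4 is recovered with calibrated coverage", {
  d <- make_survival_sample(5000, hr = 1.4, seed = 7)
  fit <- cox_fit(d, "grp")
  expect_gt(fit$conf_high, 1.4)
  expect_lt(fit$conf_low, 1.4)

  covered <- 0L
  for (seed in 1:20) {
    f <- cox_fit(make_survival_sample(2000, hr = 1.4, seed = 100 + seed), "grp")
    if (f$conf_low < 1.4 && f$conf_high > 1.4) covered <- covered + 1L
  }
  expect_gte(covered, 18L)
})

test_that("risk difference and NNH arithmetic is exact and flags non-harm", {
  res <- risk_difference_and_nnh(0.143, 0.112)
  expect_equal(res$risk_difference, 0.031)
  expect_equal(res$nnh_rounded, 32)

  flat <- risk_difference_and_nnh(0.5, 0.5)
  expect_false(flat$nnh_defined)
  expect_true(is.na(flat$nnh))

  expect_equal(risk_difference_and_nnh(0.2, 0.1)$nnh, 10)
  expect_error(risk_difference_and_nnh(1.2, 0.1), class = "g6pd_invalid_input")
})

test_that("generated cohorts show the planted deficiency hazard in expectation", {
  n_seeds <- 5
  hr_def <- numeric(n_seeds)
  incidences <- matrix(NA_real_, n_seeds, 3,
                       dimnames = list(NULL, c("general", "possible", "likely")))
  hr_strata <- matrix(NA_real_, n_seeds, 2,
                      dimnames = list(NULL, c("possible", "likely")))
  covs <- c("age", "sex", "smoking", "diabetes_duration", "ldl", "hypertension")
  for (i in seq_len(n_seeds)) {
    b <- generate_cohort(synthetic_config(n_participants = 20000, seed = i))
    cohort <- build_cohort(b$participants, b$draws, b$genotypes)
    screen <- screen_cohort(cohort)
    rec <- dplyr::inner_join(b$survival, screen, by = "participant_id")
    s <- suppressWarnings(survival_summary(rec, covariates = covs))
    incidences[i, ] <- c(s$incidence_reference[1], s$incidence_exposed[1],
                         s$incidence_exposed[2])
    hr_strata[i, ] <- s$hr

    gen <- dplyr::inner_join(
      dplyr::select(b$genotypes, "participant_id", gsex = "sex", "allele_count"),
      rec, by = "participant_id"
    )
    gen$deficient <- as.character(
      zygosity_from_allele_count(gen$gsex, gen$allele_count)
    ) %in% c("var_hemizygote", "var_homozygote")
    hr_def[i] <- cox_fit(gen, "deficient", covariates = covs)$hr[1]
  }
  # the planted deficiency hazard ratio is recovered directly
  expect_true(all(hr_def > 1))
  expect_lt(abs(mean(hr_def) - 1.4), 0.35)
  # predicted strata are enriched: seed-averaged incidence ordering holds
  means <- colMeans(incidences)
  expect_gte(means["likely"], means["possible"])
  expect_gte(means["possible"], means["general"])
  # and the fitted stratum contrasts exceed 1 in the majority of seeds
  expect_gte(sum(hr_strata[, "possible"] > 1), 3)
  expect_gte(sum(hr_strata[, "likely"] > 1), 3)
})
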