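test_that("generation is deterministic and preserves the caller's RNG", {
  cfg <- synthetic_config(n_participants = 400, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_equal(a$participants, b$participants)
  expect_equal(a$draws, b$draws)
  expect_equal(a$genotypes, b$genotypes)
  expect_equal(a$survival, b$survival)

  # the caller's RNG stream continues as if nothing was drawn
  set.seed(123)
  r1 <- runif(1)
  invisible(generate_cohort(cfg))
  r2 <- runif(1)
  set.seed(123)
  expect_equal(c(runif(1), runif(1)), c(r1, r2))
})

test_that("fixtures are byte-identical across runs of the same config", {
  cfg <- synthetic_config(n_participants = 150, seed = 12)
  d1 <- file.path(tempfile(), "a")
  d2 <- file.path(tempfile(), "b")
  write_fixture(generate_cohort(cfg), d1)
  write_fixture(generate_cohort(cfg), d2)
  for (f in c("participants.csv", "labs.csv", "genotypes.csv", "genotypes.vcf",
              "survival.csv", "manifest.yaml")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("zygosity frequencies track Hardy-Weinberg at the configured q", {
  b <- generate_cohort(synthetic_config(n_participants = 10000, q = 0.12, seed = 42))
  g <- b$genotypes
  males <- g[g$sex == "male", ]
  females <- g[g$sex == "female", ]
  hemi_frac <- mean(males$allele_count == 1)
  se_hemi <- sqrt(0.12 * 0.88 / nrow(males))
  expect_lt(abs(hemi_frac - 0.12), 3 * se_hemi)
  hom_frac <- mean(females$allele_count == 2)
  se_hom <- sqrt(0.0144 * (1 - 0.0144) / nrow(females))
  expect_lt(abs(hom_frac - 0.0144), 3 * se_hom)
})

test_that("zero effect shifts give chance-level discrimination", {
  cfg_null <- synthetic_config(n_participants = 6000, hba1c_shift_full = 0,
                               rdw_shift_full = 0, seed = 31)
  b <- generate_cohort(cfg_null)
  cohort <- build_cohort(b$participants, b$draws, b$genotypes)
  males <- cohort[cohort$sex == "male", ]
  truth <- as.character(males$zygosity) == "var_hemizygote"
  # partition fitted on one half, scored on the other, so overfit noise
  # splits cannot inflate the statistic
  half <- seq_len(nrow(males)) %% 2 == 0
  fit <- learn_rule(males$rdw[half], males$glucose_gap[half], truth[half])
  scores <- predict(fit, males$rdw[!half], males$glucose_gap[!half])
  res <- auroc(scores, truth[!half], n_boot = 300, seed = 8)
  expect_lt(abs(res$auroc - 0.5), 3 * max(res$sd, 0.01))
})

test_that("the HbA1c shift surfaces as a glucose-gap separation above 10 mg/dL", {
  b <- generate_cohort(synthetic_config(seed = 1))
  cohort <- build_cohort(b$participants, b$draws, b$genotypes)
  males <- cohort[cohort$sex == "male", ]
  deficient <- as.character(males$zygosity) == "var_hemizygote"
  expect_gt(mean(males$glucose_gap[deficient]) - mean(males$glucose_gap[!deficient]),
            10)
})

test_that("the likely rule enriches male hemizygotes at least 2-fold", {
  b <- generate_cohort(synthetic_config(n_participants = 8000, seed = 1))
  cohort <- build_cohort(b$participants, b$draws, b$genotypes)
  screen <- screen_cohort(cohort)
  grid <- evaluate_stratified(cohort, screen)
  row <- grid[grid$task == "male_hemizygote" & grid$cohort == "Overall" &
                grid$criterion == "likely", ]
  expect_gt(row$precision, 2 * row$prevalence)
})

test_that("recall of possible dominates recall of likely on every stratum", {
  b <- generate_cohort(synthetic_config(n_participants = 8000, seed = 2))
  cohort <- build_cohort(b$participants, b$draws, b$genotypes)
  grid <- evaluate_stratified(cohort, screen_cohort(cohort))
  wide <- merge(
    grid[grid$criterion == "possible", c("task", "cohort", "recall")],
    grid[grid$criterion == "likely", c("task", "cohort", "recall")],
    by = c("task", "cohort"), suffixes = c("_possible", "_likely")
  )
  defined <- !is.na(wide$recall_possible) & !is.na(wide$recall_likely)
  expect_true(any(defined))
  expect_true(all(wide$recall_possible[defined] >= wide$recall_likely[defined]))
})

test_that("fixture writing keeps row counts and survives a round trip", {
  b <- generate_cohort(synthetic_config(n_participants = 200, seed = 6))
  dir <- tempfile()
  paths <- write_fixture(b, dir)
  expect_true(all(file.exists(paths)))
  labs <- readr::read_csv(paths[["labs"]], show_col_types = FALSE)
  expect_equal(length(unique(labs$participant_id)), 200)

  participants <- readr::read_csv(paths[["participants"]], show_col_types = FALSE)
  genotypes <- readr::read_csv(paths[["genotypes"]], show_col_types = FALSE)
  cohort <- build_cohort(participants, labs, genotypes)
  expect_equal(nrow(cohort) + sum(exclusion_ledger(cohort)$n[-1]), 200)

  # degenerate cohort: header-only files
  empty_dir <- tempfile()
  write_fixture(generate_cohort(synthetic_config(n_participants = 0, seed = 1)),
                empty_dir)
  expect_equal(nrow(readr::read_csv(file.path(empty_dir, "labs.csv"),
                                    show_col_types = FALSE)), 0)
})

test_that("invalid generator configurations name their offending fields", {
  err <- tryCatch(synthetic_config(q = 1.5, rdw_sd = -1), error = identity)
  expect_s3_class(err, "g6pd_config_error")
  expect_match(conditionMessage(err), "q")
  expect_match(conditionMessage(err), "rdw_sd")
})
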