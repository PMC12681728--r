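test_that("precision and recall follow the prose definitions", {
  # toy confusion table: TP = 8, test-positive = 10, genotype-positive = 16
  truth <- rep(c(TRUE, FALSE), c(16, 4))
  predicted <- c(rep(TRUE, 8), rep(FALSE, 8), rep(TRUE, 2), rep(FALSE, 2))
  pr <- precision_recall(predicted, truth)
  expect_equal(pr$tp, 8)
  expect_equal(pr$precision, 0.80)
  expect_equal(pr$recall, 0.50)

  # empty denominators are flagged, never coerced
  none <- precision_recall(rep(FALSE, 5), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_false(none$precision_defined)
  expect_true(is.na(none$precision))
  expect_equal(none$recall, 0)

  all_pos <- precision_recall(rep(TRUE, 4), rep(TRUE, 4))
  expect_equal(all_pos$precision, 1)
  expect_equal(all_pos$recall, 1)
})

test_that("rank AUROC equals the pairwise brute force, with midrank ties", {
  expect_equal(auroc(c(1, 2, 3, 10, 11), rep(c(FALSE, TRUE), c(3, 2)),
                     n_boot = 0)$auroc, 1)
  # hand-enumerated: positive-negative wins 3 of 4 pairs
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE),
                     n_boot = 0)$auroc, 0.75)

  set.seed(23)
  for (rep in 1:6) {
    n <- sample(20:200, 1)
    scores <- sample(round(runif(n, 0, 5), 1)) # heavy ties
    truth <- runif(n) < 0.4
    if (!any(truth) || all(truth)) next
    expect_equal(auroc(scores, truth, n_boot = 0)$auroc,
                 oracle_pairwise_auc(scores, truth))
  }
  expect_error(auroc(1:4, rep(TRUE, 4), n_boot = 0),
               class = "g6pd_degenerate_labels")
})

test_that("permuted scores give chance-level AUROC within bootstrap uncertainty", {
  set.seed(5)
  truth <- rep(c(TRUE, FALSE), c(300, 700))
  scores <- rnorm(1000) # independent of truth
  res <- auroc(scores, truth, n_boot = 300, seed = 99)
  expect_lt(abs(res$auroc - 0.5), 3 * res$sd)
  # seeded bootstrap is reproducible and preserves the caller's RNG stream
  before <- runif(1)
  res2 <- auroc(scores, truth, n_boot = 300, seed = 99)
  expect_equal(res$sd, res2$sd)
})

test_that("the stratified grid matches hand-computed values on a small fixture", {
  # 12 males in two pseudo-cohorts; hand-tallied confusion counts
  cohort <- tibble::tibble(
    participant_id = sprintf("M%02d", 1:12),
    sex = "male",
    zygosity = factor(
      rep(c("var_hemizygote", "ref_hemizygote"), c(4, 8)),
      levels = c("ref_hemizygote", "var_hemizygote", "ref_homozygote",
                 "heterozygote", "var_homozygote")
    ),
    cohort_label = rep(c("X", "Y"), 6)
  )
  screen <- tibble::tibble(
    participant_id = cohort$participant_id,
    possible = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE,
                 FALSE, FALSE, FALSE, FALSE),
    likely = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
               FALSE, FALSE, FALSE, FALSE)
  )
  grid <- evaluate_stratified(cohort, screen)
  overall_poss <- grid[grid$task == "male_hemizygote" & grid$cohort == "Overall" &
                         grid$criterion == "possible", ]
  # TP = 3 of 5 test-positives; 4 genotype-positives of 12
  expect_equal(overall_poss$true_positive, 3)
  expect_equal(overall_poss$precision, 3 / 5)
  expect_equal(overall_poss$recall, 3 / 4)
  expect_equal(overall_poss$prevalence, 4 / 12)

  overall_lik <- grid[grid$task == "male_hemizygote" & grid$cohort == "Overall" &
                        grid$criterion == "likely", ]
  expect_equal(overall_lik$true_positive, 2)
  expect_equal(overall_lik$precision, 1)
  expect_equal(overall_lik$recall, 2 / 4)

  # pooled Overall TP equals the sum of per-cohort TPs
  per_cohort <- grid[grid$task == "male_hemizygote" & grid$cohort != "Overall" &
                       grid$criterion == "possible", ]
  expect_equal(sum(per_cohort$true_positive), overall_poss$true_positive)

  # female tasks have no genotype-positives here: recall flagged undefined
  fem <- grid[grid$task == "female_homozygote" & grid$cohort == "Overall" &
                grid$criterion == "possible", ]
  expect_equal(nrow(fem), 1)
  expect_false(fem$recall_defined)
})

test_that("two identical cohorts pool to the same rates", {
  base <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:10),
    sex = "male",
    zygosity = factor(rep(c("var_hemizygote", "ref_hemizygote"), c(3, 7)),
                      levels = c("ref_hemizygote", "var_hemizygote",
                                 "ref_homozygote", "heterozygote", "var_homozygote")),
    cohort_label = "A"
  )
  twin <- base
  twin$participant_id <- sprintf("Q%02d", 1:10)
  twin$cohort_label <- "B"
  cohort <- dplyr::bind_rows(base, twin)
  screen <- tibble::tibble(
    participant_id = cohort$participant_id,
    possible = rep(c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE), 2),
    likely = rep(c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE), 2)
  )
  grid <- evaluate_stratified(cohort, screen)
  task <- grid[grid$task == "male_hemizygote" & grid$criterion == "possible", ]
  a <- task[task$cohort == "A", ]
  overall <- task[task$cohort == "Overall", ]
  expect_equal(overall$precision, a$precision)
  expect_equal(overall$recall, a$recall)
  expect_equal(overall$prevalence, a$prevalence)
})

test_that("misaligned ids and unknown cohort labels are rejected", {
  cohort <- tibble::tibble(
    participant_id = "A", sex = "male",
    zygosity = factor("var_hemizygote",
                      levels = c("ref_hemizygote", "var_hemizygote",
                                 "ref_homozygote", "heterozygote", "var_homozygote")),
    cohort_label = "siteX"
  )
  screen <- tibble::tibble(participant_id = "B", possible = TRUE, likely = TRUE)
  expect_error(evaluate_stratified(cohort, screen), class = "g6pd_data_integrity")

  screen$participant_id <- "A"
  expect_error(evaluate_stratified(cohort, screen, cohorts = c("siteA", "siteB")),
               class = "g6pd_config_error")
})

test_that("rank AUROC agrees with pROC on a realistic score vector", {
  skip_if_not_installed("pROC")
  set.seed(71)
  truth <- runif(400) < 0.2
  scores <- rnorm(400) + 1.2 * truth
  ours <- auroc(scores, truth, n_boot = 0)$auroc
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE))))
  expect_equal(ours, ref, tolerance = 1e-12)
})
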