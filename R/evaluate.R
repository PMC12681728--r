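# Stratified screening evaluation: precision, recall, AUROC, and the
# (sex x zygosity-task x cohort) evaluation grid.

#' The three screening tasks
#'
#' The algorithm is evaluated against three target populations: (1) male
#' variant hemizygotes, (2) female variant homozygotes, and (3) females
#' carrying at least one variant allele (heterozygotes or homozygotes).
#'
#' @return A named list of task definitions, each with `name`, `sex`, and
#'   `positive_zygosities`.
#' @export
default_tasks <- function() {
  list(
    male_hemizygote = list(
      name = "male_hemizygote", sex = "male",
      positive_zygosities = "var_hemizygote"
    ),
    female_homozygote = list(
      name = "female_homozygote", sex = "female",
      positive_zygosities = "var_homozygote"
    ),
    female_het_or_hom = list(
      name = "female_het_or_hom", sex = "female",
      positive_zygosities = c("heterozygote", "var_homozygote")
    )
  )
}

#' Precision and recall of a screen against genotype truth
#'
#' Precision is TP / test-positives and recall is TP / genotype-positives,
#' where a true positive is a participant who both meets the screening
#' criterion and carries the relevant genotype. Empty denominators yield an
#' `NA` ratio together with an explicit defined-flag — never a silent 0 or 1.
#'
#' @param predicted Logical vector: screen positives.
#' @param truth Logical vector: genotype positives, aligned with `predicted`.
#' @return List with `tp`, `test_positive`, `genotype_positive`, `n`,
#'   `precision`, `recall`, `precision_defined`, `recall_defined`.
#' @examples
#' precision_recall(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE))
#' @export
precision_recall <- function(predicted, truth) {
  if (!is.logical(predicted) || !is.logical(truth) ||
      length(predicted) != length(truth)) {
    abort_invalid("`predicted` and `truth` must be aligned logical vectors.")
  }
  if (anyNA(predicted) || anyNA(truth)) {
    abort_invalid("`predicted` and `truth` must not contain missing values.")
  }
  tp <- sum(predicted & truth)
  test_pos <- sum(predicted)
  geno_pos <- sum(truth)
  list(
    tp = tp,
    test_positive = test_pos,
    genotype_positive = geno_pos,
    n = length(truth),
    precision = if (test_pos > 0) tp / test_pos else NA_real_,
    recall = if (geno_pos > 0) tp / geno_pos else NA_real_,
    precision_defined = test_pos > 0,
    recall_defined = geno_pos > 0
  )
}

#' Rank-based AUROC with bootstrap uncertainty
#'
#' Computes the area under the receiver-operating curve as the Mann-Whitney
#' rank statistic with midrank tie handling: the probability that a randomly
#' chosen positive scores above a randomly chosen negative, ties counting
#' one half. Uncertainty is the standard deviation of the statistic over a
#' seeded nonparametric bootstrap; resamples that lose one class are dropped.
#'
#' @param scores Numeric score vector (higher = more positive-like).
#' @param truth Logical labels; both classes must be present.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Optional integer seed for the bootstrap; the caller's RNG
#'   state is preserved.
#' @return List with `auroc`, `sd` (bootstrap SD, `NA` if `n_boot = 0`), and
#'   `n_boot_effective`.
#' @examples
#' auroc(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE), n_boot = 0)
#' @export
auroc <- function(scores, truth, n_boot = 1000, seed = NULL) {
  check_numeric_finite(scores, "scores")
  if (!is.logical(truth) || length(truth) != length(scores) || anyNA(truth)) {
    abort_invalid("`truth` must be a complete logical vector aligned with `scores`.")
  }
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L) {
    abort_degenerate("AUROC requires both classes in `truth`.")
  }
  point <- auc_rank(scores, truth)
  sd_boot <- NA_real_
  n_eff <- 0L
  if (n_boot > 0) {
    boot <- function() {
      vals <- numeric(n_boot)
      for (b in seq_len(n_boot)) {
        idx <- sample.int(length(truth), replace = TRUE)
        tb <- truth[idx]
        vals[b] <- if (any(tb) && any(!tb)) auc_rank(scores[idx], tb) else NA_real_
      }
      vals
    }
    vals <- if (is.null(seed)) boot() else with_local_seed(seed, boot())
    sd_boot <- stats::sd(vals, na.rm = TRUE)
    n_eff <- sum(!is.na(vals))
  }
  list(auroc = point, sd = sd_boot, n_boot_effective = n_eff)
}

auc_rank <- function(scores, truth) {
  r <- rank(scores) # midranks for ties
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified evaluation grid
#'
#' Builds the full evaluation grid — prevalence, recall, and precision per
#' (task, cohort, criterion) — for the three screening tasks, including an
#' `"Overall"` row per task that pools counts (not rates) across cohorts.
#'
#' @param cohort Analysis table from [build_cohort()] with `participant_id`,
#'   `sex`, `zygosity`, and a cohort-label column.
#' @param screen Screen results from [screen_cohort()] with `participant_id`,
#'   `possible`, `likely`, covering the same participants.
#' @param tasks Task definitions, as from [default_tasks()].
#' @param cohort_col Name of the cohort-label column (default
#'   `"cohort_label"`).
#' @param cohorts Optional character vector of expected cohort labels; a row
#'   carrying any other label raises a configuration error.
#' @return Tibble with one row per (task, cohort incl. "Overall", criterion):
#'   counts (`n`, `genotype_positive`, `test_positive`, `true_positive`) and
#'   proportions (`prevalence`, `recall`, `precision`, `NA` when undefined).
#' @export
evaluate_stratified <- function(cohort, screen, tasks = default_tasks(),
                                cohort_col = "cohort_label", cohorts = NULL) {
  validate_columns(cohort, c("participant_id", "sex", "zygosity", cohort_col),
                   "analysis table")
  validate_columns(screen, c("participant_id", "possible", "likely"),
                   "screen results")
  if (!setequal(cohort$participant_id, screen$participant_id)) {
    abort_integrity("analysis table and screen results cover different participants.")
  }
  data <- dplyr::inner_join(cohort, screen, by = "participant_id")
  labels <- unique(data[[cohort_col]])
  if (!is.null(cohorts)) {
    unknown <- setdiff(labels, cohorts)
    if (length(unknown) > 0L) {
      abort_config(sprintf("unknown cohort label(s): %s.",
                           paste(unknown, collapse = ", ")))
    }
    labels <- cohorts
  } else {
    labels <- sort(labels)
  }

  out <- list()
  for (task in tasks) {
    in_task <- data[data$sex == task$sex, , drop = FALSE]
    truth_all <- as.character(in_task$zygosity) %in% task$positive_zygosities
    for (coh in c(labels, "Overall")) {
      sel <- if (coh == "Overall") rep(TRUE, nrow(in_task)) else in_task[[cohort_col]] == coh
      truth <- truth_all[sel]
      for (criterion in c("possible", "likely")) {
        pr <- precision_recall(in_task[[criterion]][sel], truth)
        out[[length(out) + 1L]] <- tibble::tibble(
          task = task$name, cohort = coh, criterion = criterion,
          n = pr$n, genotype_positive = pr$genotype_positive,
          test_positive = pr$test_positive, true_positive = pr$tp,
          prevalence = if (pr$n > 0) pr$genotype_positive / pr$n else NA_real_,
          recall = pr$recall, precision = pr$precision,
          recall_defined = pr$recall_defined,
          precision_defined = pr$precision_defined
        )
      }
    }
  }
  dplyr::bind_rows(out)
}
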