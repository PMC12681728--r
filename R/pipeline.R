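# Pipeline plumbing: configuration, table IO with column mapping, run logs,
# and the subcommand dispatcher behind the command-line wrapper in
# inst/cli/g6pdscreen.R.

#' Assemble (or read) a pipeline configuration
#'
#' The configuration drives every subcommand of [run_pipeline()]: where the
#' fixture tables live, where artifacts go, the decision thresholds, the
#' fasting semantics, the survival horizon, and the seed. `column_map` lets
#' input files use their own column headers: it is a named list mapping the
#' pipeline's canonical names (e.g. `glucose`) to the file's headers.
#'
#' @param input_dir Directory holding the input tables (as written by
#'   [write_fixture()]).
#' @param output_dir Directory for artifacts (created if needed).
#' @param rdw_threshold,gg_threshold Decision thresholds (defaults 12, -15).
#' @param fasting_assured Per-run fasting semantics for
#'   [filter_eligible_draws()].
#' @param horizon Survival horizon in years (default 20).
#' @param n_boot Bootstrap resamples for AUROC uncertainty.
#' @param seed Integer seed for seeded steps (simulation, bootstrap).
#' @param n_participants Cohort size used by the `simulate` subcommand.
#' @param column_map Optional named list of canonical -> file column names.
#' @param positive_zygosities Zygosity labels treated as genotype-positive by
#'   `learn-thresholds` (default hemizygotes plus homozygotes; heterozygote
#'   inclusion is a user choice).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = ".", output_dir = "g6pd-artifacts",
                            rdw_threshold = 12, gg_threshold = -15,
                            fasting_assured = FALSE, horizon = 20,
                            n_boot = 1000, seed = 1, n_participants = 4000,
                            column_map = NULL,
                            positive_zygosities = c("var_hemizygote", "var_homozygote")) {
  structure(
    list(input_dir = input_dir, output_dir = output_dir,
         rdw_threshold = rdw_threshold, gg_threshold = gg_threshold,
         fasting_assured = fasting_assured, horizon = horizon,
         n_boot = n_boot, seed = seed, n_participants = n_participants,
         column_map = column_map, positive_zygosities = positive_zygosities),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys raise a configuration error; omitted keys take the
#' [pipeline_config()] defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config file not found: %s.", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    abort_config(sprintf("unknown config key(s): %s.", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

# Read a CSV with the documented dialect ("." and empty are missing) and
# apply the canonical column mapping.
read_pipeline_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) abort_config(sprintf("input file not found: %s.", path))
  df <- readr::read_csv(path, na = c("", ".", "NA"), show_col_types = FALSE)
  if (!is.null(column_map)) {
    for (canonical in names(column_map)) {
      from <- column_map[[canonical]]
      if (from %in% names(df)) {
        names(df)[names(df) == from] <- canonical
      }
    }
  }
  tibble::as_tibble(df)
}

write_run_log <- function(path, config, step, counts) {
  lines <- c(
    sprintf("tool: g6pdscreen %s", as.character(utils::packageVersion("g6pdscreen"))),
    sprintf("step: %s", step),
    sprintf("config_hash: %s", rlang::hash(unclass(config))),
    sprintf("seed: %s", config$seed),
    vapply(names(counts), function(k) sprintf("rows_%s: %d", k, counts[[k]]),
           character(1))
  )
  writeLines(lines, path)
}

#' Run one pipeline stage
#'
#' Dispatches the named subcommand against a [pipeline_config()]. Each stage
#' reads its inputs from `config$input_dir` (or the artifacts of earlier
#' stages in `config$output_dir`), writes its artifact plus a run log
#' carrying the tool version, configuration hash, seed, and row counts, and
#' never mutates its inputs.
#'
#' Stages: `simulate` (write a synthetic fixture), `build-cohort`
#' (analysis table + exclusion ledger), `classify` (screen results),
#' `learn-thresholds` (threshold JSON), `evaluate` (stratified grid CSV
#' mirroring the published evaluation layout), `survival` (stratum
#' contrasts), and `report` (assembled JSON summary).
#'
#' @param subcommand One of the stage names above.
#' @param config A [pipeline_config()] or path to a YAML config.
#' @return Invisibly, the paths of the artifacts written.
#' @export
run_pipeline <- function(subcommand, config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  subcommand <- match.arg(subcommand, c("simulate", "build-cohort", "classify",
                                        "learn-thresholds", "evaluate",
                                        "survival", "report"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)
  criteria <- decision_criteria(config$rdw_threshold, config$gg_threshold)

  if (subcommand == "simulate") {
    bundle <- generate_cohort(synthetic_config(
      n_participants = config$n_participants, seed = config$seed
    ))
    paths <- write_fixture(bundle, config$input_dir)
    write_run_log(out("simulate.log"), config, "simulate",
                  list(participants = nrow(bundle$participants),
                       draws = nrow(bundle$draws)))
    return(invisible(paths))
  }

  if (subcommand == "build-cohort") {
    participants <- read_pipeline_table(file.path(config$input_dir, "participants.csv"),
                                        config$column_map)
    draws <- read_pipeline_table(file.path(config$input_dir, "labs.csv"),
                                 config$column_map)
    genotypes <- read_pipeline_table(file.path(config$input_dir, "genotypes.csv"),
                                     config$column_map)
    validate_columns(draws, c("participant_id", "draw_date", "glucose", "hba1c", "rdw"),
                     "labs.csv")
    cohort <- build_cohort(participants, draws, genotypes,
                           fasting_assured = config$fasting_assured)
    readr::write_csv(cohort, out("analysis_table.csv"))
    readr::write_csv(exclusion_ledger(cohort), out("exclusion_ledger.csv"))
    write_run_log(out("build-cohort.log"), config, "build-cohort",
                  list(analysis = nrow(cohort)))
    return(invisible(c(analysis = out("analysis_table.csv"),
                       ledger = out("exclusion_ledger.csv"))))
  }

  if (subcommand == "classify") {
    cohort <- read_pipeline_table(out("analysis_table.csv"))
    screen <- screen_cohort(cohort, criteria)
    readr::write_csv(screen, out("screen_results.csv"))
    write_run_log(out("classify.log"), config, "classify",
                  list(screen = nrow(screen)))
    return(invisible(c(screen = out("screen_results.csv"))))
  }

  if (subcommand == "learn-thresholds") {
    cohort <- read_pipeline_table(out("analysis_table.csv"))
    validate_columns(cohort, c("rdw", "glucose_gap", "zygosity"), "analysis table")
    labels <- cohort$zygosity %in% config$positive_zygosities
    fit <- learn_rule(cohort$rdw, cohort$glucose_gap, labels)
    res <- list(
      rdw_threshold = fit$rdw_threshold, rdw_direction = fit$rdw_direction,
      gg_threshold = fit$gg_threshold, gg_direction = fit$gg_direction,
      root_feature = fit$root_feature,
      root_impurity_decrease = fit$root_impurity_decrease,
      second_impurity_decrease = fit$second_impurity_decrease,
      n = fit$n, n_positive = fit$n_positive
    )
    jsonlite::write_json(res, out("thresholds.json"), auto_unbox = TRUE, digits = NA)
    write_run_log(out("learn-thresholds.log"), config, "learn-thresholds",
                  list(analysis = nrow(cohort)))
    return(invisible(c(thresholds = out("thresholds.json"))))
  }

  if (subcommand == "evaluate") {
    cohort <- read_pipeline_table(out("analysis_table.csv"))
    screen <- read_pipeline_table(out("screen_results.csv"))
    grid <- evaluate_stratified(cohort, screen)
    formatted <- tibble::tibble(
      sex = ifelse(grid$task == "male_hemizygote", "male", "female"),
      zygosity_task = grid$task,
      cohort = grid$cohort,
      criterion = grid$criterion,
      n = grid$n,
      prevalence_pct = round(100 * grid$prevalence, 1),
      recall_pct = round(100 * grid$recall, 1),
      precision_pct = round(100 * grid$precision, 1)
    )
    readr::write_csv(grid, out("evaluation_grid.csv"))
    readr::write_csv(formatted, out("evaluation_grid_pct.csv"))
    write_run_log(out("evaluate.log"), config, "evaluate",
                  list(grid = nrow(grid)))
    return(invisible(c(grid = out("evaluation_grid.csv"),
                       formatted = out("evaluation_grid_pct.csv"))))
  }

  if (subcommand == "survival") {
    surv <- read_pipeline_table(file.path(config$input_dir, "survival.csv"))
    screen <- read_pipeline_table(out("screen_results.csv"))
    records <- dplyr::inner_join(surv, screen, by = "participant_id")
    summary <- survival_summary(
      records,
      covariates = c("age", "sex", "smoking", "diabetes_duration", "ldl", "hypertension"),
      horizon = config$horizon
    )
    readr::write_csv(summary, out("survival_summary.csv"))
    jsonlite::write_json(summary, out("survival_summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    write_run_log(out("survival.log"), config, "survival",
                  list(records = nrow(records)))
    return(invisible(c(summary = out("survival_summary.csv"))))
  }

  # report: assemble cohort-description and evaluation summaries
  cohort <- read_pipeline_table(out("analysis_table.csv"))
  grid <- read_pipeline_table(out("evaluation_grid.csv"))
  labs_summary <- cohort |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(
      n = dplyr::n(),
      hba1c_median = stats::median(.data$hba1c),
      glucose_median = stats::median(.data$glucose),
      glucose_gap_median = stats::median(.data$glucose_gap),
      rdw_median = stats::median(.data$rdw),
      .groups = "drop"
    )
  zyg <- cohort |>
    dplyr::count(.data$sex, .data$zygosity) |>
    dplyr::group_by(.data$sex) |>
    dplyr::mutate(pct = round(100 * .data$n / sum(.data$n), 1)) |>
    dplyr::ungroup()
  report <- list(
    labs_by_sex = labs_summary,
    zygosity_by_sex = zyg,
    evaluation_grid = grid
  )
  surv_path <- out("survival_summary.csv")
  if (file.exists(surv_path)) {
    report$survival <- read_pipeline_table(surv_path)
  }
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  write_run_log(out("report.log"), config, "report",
                list(analysis = nrow(cohort), grid = nrow(grid)))
  invisible(c(report = out("report.json")))
}
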