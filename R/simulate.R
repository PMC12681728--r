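# Seeded synthetic EHR-style cohort generator. Emulates the statistical
# structure the screening pipeline assumes: X-linked genotypes at allele
# frequency q under Hardy-Weinberg equilibrium, a glycation relationship
# between per-participant mean glucose and HbA1c with a downward HbA1c shift
# in variant hemizygotes/homozygotes (partially expressed in heterozygotes
# via an X-inactivation mosaicism multiplier), a downward RDW shift in the
# same groups, multiple fasting/non-fasting draws per participant, and an
# elevated retinopathy hazard in deficiency-affected diabetics.

#' Configuration for the synthetic cohort generator
#'
#' All generative parameters of [generate_cohort()] with their default study
#' conditions. Effect directions mirror the physiology (HbA1c and RDW
#' shifted down in variant carriers; retinopathy hazard elevated in
#' deficiency-affected diabetics); magnitudes are the generator's own
#' documented choices, recorded in the fixture manifest.
#'
#' @param n_participants Number of participants.
#' @param female_fraction Proportion female.
#' @param q Variant allele frequency.
#' @param glucose_mean_nondiabetic,glucose_sd_nondiabetic Per-participant
#'   mean fasting glucose distribution, non-diabetics (mg/dL).
#' @param glucose_mean_diabetic,glucose_sd_diabetic Same for diabetics.
#' @param diabetes_prevalence Proportion with diabetes.
#' @param hba1c_shift_full Downward HbA1c shift (%, NGSP) in hemizygotes and
#'   homozygotes.
#' @param hba1c_noise_sd Per-draw HbA1c measurement noise SD (%).
#' @param rdw_mean,rdw_sd Per-participant RDW distribution (RDW units).
#' @param rdw_shift_full Downward RDW shift in hemizygotes/homozygotes.
#' @param rdw_noise_sd Per-draw RDW measurement noise SD.
#' @param draws_min,draws_max Range of draws per participant.
#' @param fasting_probability Probability a draw is fasting.
#' @param nonfasting_bump_mean Mean of the Gamma-distributed post-prandial
#'   glucose elevation on non-fasting draws (mg/dL).
#' @param draw_glucose_sd Per-draw glucose noise SD (mg/dL).
#' @param retinopathy_base_hazard Baseline retinopathy hazard per year among
#'   diabetics.
#' @param deficiency_hazard_ratio Hazard multiplier for deficiency-affected
#'   (hemizygous/homozygous) diabetics.
#' @param censor_min,censor_max Administrative censoring time range (years).
#' @param g6pd_dx_rate Probability a true carrier holds a clinical
#'   G6PD-deficiency diagnosis code (carriers are rarely diagnosed).
#' @param cohort_labels Pseudo-cohort labels partitioning the population for
#'   the stratified evaluation grid.
#' @param seed Integer RNG seed; generation is fully reproducible from it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_participants = 4000,
                             female_fraction = 0.5,
                             q = 0.12,
                             glucose_mean_nondiabetic = 90,
                             glucose_sd_nondiabetic = 8,
                             glucose_mean_diabetic = 150,
                             glucose_sd_diabetic = 30,
                             diabetes_prevalence = 0.3,
                             hba1c_shift_full = -0.75,
                             hba1c_noise_sd = 0.25,
                             rdw_mean = 13.9,
                             rdw_sd = 1.1,
                             rdw_shift_full = -1.8,
                             rdw_noise_sd = 0.5,
                             draws_min = 1,
                             draws_max = 4,
                             fasting_probability = 0.6,
                             nonfasting_bump_mean = 40,
                             draw_glucose_sd = 10,
                             retinopathy_base_hazard = 0.006,
                             deficiency_hazard_ratio = 1.4,
                             censor_min = 5,
                             censor_max = 25,
                             g6pd_dx_rate = 0.004,
                             cohort_labels = c("site_A", "site_B", "site_C", "site_D"),
                             seed = 1) {
  cfg <- list(
    n_participants = n_participants, female_fraction = female_fraction, q = q,
    glucose_mean_nondiabetic = glucose_mean_nondiabetic,
    glucose_sd_nondiabetic = glucose_sd_nondiabetic,
    glucose_mean_diabetic = glucose_mean_diabetic,
    glucose_sd_diabetic = glucose_sd_diabetic,
    diabetes_prevalence = diabetes_prevalence,
    hba1c_shift_full = hba1c_shift_full, hba1c_noise_sd = hba1c_noise_sd,
    rdw_mean = rdw_mean, rdw_sd = rdw_sd, rdw_shift_full = rdw_shift_full,
    rdw_noise_sd = rdw_noise_sd,
    draws_min = draws_min, draws_max = draws_max,
    fasting_probability = fasting_probability,
    nonfasting_bump_mean = nonfasting_bump_mean,
    draw_glucose_sd = draw_glucose_sd,
    retinopathy_base_hazard = retinopathy_base_hazard,
    deficiency_hazard_ratio = deficiency_hazard_ratio,
    censor_min = censor_min, censor_max = censor_max,
    g6pd_dx_rate = g6pd_dx_rate, cohort_labels = cohort_labels, seed = seed
  )
  offenders <- character(0)
  prop_fields <- c("female_fraction", "q", "diabetes_prevalence",
                   "fasting_probability", "g6pd_dx_rate")
  for (f in prop_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      offenders <- c(offenders, f)
    }
  }
  pos_fields <- c("glucose_sd_nondiabetic", "glucose_sd_diabetic",
                  "hba1c_noise_sd", "rdw_sd", "rdw_noise_sd", "draw_glucose_sd",
                  "glucose_mean_nondiabetic", "glucose_mean_diabetic", "rdw_mean",
                  "nonfasting_bump_mean", "retinopathy_base_hazard",
                  "deficiency_hazard_ratio", "censor_min", "censor_max")
  for (f in pos_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      offenders <- c(offenders, f)
    }
  }
  if (!is.numeric(n_participants) || length(n_participants) != 1L ||
      is.na(n_participants) || n_participants < 0 ||
      n_participants != as.integer(n_participants)) {
    offenders <- c(offenders, "n_participants")
  }
  if (!is.numeric(draws_min) || !is.numeric(draws_max) || draws_min < 1 ||
      draws_max < draws_min) {
    offenders <- c(offenders, "draws_min/draws_max")
  }
  if (censor_max <= censor_min) offenders <- c(offenders, "censor_min/censor_max")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    offenders <- c(offenders, "seed")
  }
  if (length(offenders) > 0L) {
    abort_config(sprintf("invalid synthetic_config field(s): %s.",
                         paste(unique(offenders), collapse = ", ")))
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic EHR-style cohort
#'
#' Draws a complete cohort from a [synthetic_config()]: participant sex and
#' X-linked genotype (males Bernoulli(q), females Binomial(2, q)),
#' per-participant mean glucose by diabetes status, true HbA1c by the inverse
#' glycation relationship `(mean_glucose + 46.7) / 28.7` plus the zygosity
#' shift (full in hemizygotes/homozygotes; scaled by a Beta(2, 2)
#' X-inactivation mosaicism multiplier in heterozygotes, shared with the RDW
#' shift), per-draw laboratory noise and non-fasting glucose elevations, and
#' exponential retinopathy times for diabetics with the deficiency hazard
#' ratio applied to affected carriers. Fully reproducible from the seed; the
#' caller's RNG state is preserved.
#'
#' @param config A [synthetic_config()].
#' @return List of class `g6pd_cohort` with tibbles `participants`, `draws`,
#'   `genotypes`, `survival`, and the `config`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    abort_config("`config` must be built by `synthetic_config()`.")
  }
  with_local_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_participants
  if (n == 0L) {
    return(empty_cohort(config))
  }
  id <- sprintf("P%06d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
  allele_count <- integer(n)
  allele_count[sex == "male"] <- stats::rbinom(sum(sex == "male"), 1, config$q)
  allele_count[sex == "female"] <- stats::rbinom(sum(sex == "female"), 2, config$q)
  zygosity <- zygosity_from_allele_count(sex, allele_count)
  affected <- zygosity %in% c("var_hemizygote", "var_homozygote")
  het <- zygosity == "heterozygote"

  # X-inactivation mosaicism: one shared multiplier per heterozygote scales
  # both the HbA1c and RDW shifts.
  shift_mult <- as.numeric(affected)
  shift_mult[het] <- stats::rbeta(sum(het), 2, 2)

  diabetic <- stats::runif(n) < config$diabetes_prevalence
  mean_glucose <- ifelse(
    diabetic,
    stats::rnorm(n, config$glucose_mean_diabetic, config$glucose_sd_diabetic),
    stats::rnorm(n, config$glucose_mean_nondiabetic, config$glucose_sd_nondiabetic)
  )
  mean_glucose <- pmax(mean_glucose, 40)
  hba1c_true <- (mean_glucose + 46.7) / 28.7 + config$hba1c_shift_full * shift_mult
  rdw_true <- stats::rnorm(n, config$rdw_mean, config$rdw_sd) +
    config$rdw_shift_full * shift_mult

  g6pd_dx <- affected & stats::runif(n) < config$g6pd_dx_rate
  cohort_label <- sample(config$cohort_labels, n, replace = TRUE)

  participants <- tibble::tibble(
    participant_id = id, sex = sex,
    diabetes_flag = diabetic, g6pd_dx_flag = g6pd_dx,
    cohort_label = cohort_label
  )
  genotypes <- tibble::tibble(participant_id = id, sex = sex,
                              allele_count = allele_count)

  n_draws <- sample(seq(config$draws_min, config$draws_max), n, replace = TRUE)
  pidx <- rep(seq_len(n), n_draws)
  total <- length(pidx)
  fasting <- stats::runif(total) < config$fasting_probability
  bump <- ifelse(fasting, 0,
                 stats::rgamma(total, shape = 4,
                               scale = config$nonfasting_bump_mean / 4))
  draw_glucose <- pmax(
    mean_glucose[pidx] + bump + stats::rnorm(total, 0, config$draw_glucose_sd), 1
  )
  draw_hba1c <- pmax(hba1c_true[pidx] + stats::rnorm(total, 0, config$hba1c_noise_sd), 0.1)
  draw_rdw <- pmax(rdw_true[pidx] + stats::rnorm(total, 0, config$rdw_noise_sd), 0.1)
  draws <- tibble::tibble(
    participant_id = id[pidx],
    draw_date = as.Date("2005-01-01") + sample.int(5500, total, replace = TRUE),
    glucose = draw_glucose, hba1c = draw_hba1c, rdw = draw_rdw
  )

  # Survival stage: diabetics only, clock starting at diabetes diagnosis.
  d <- which(diabetic)
  nd <- length(d)
  hazard <- config$retinopathy_base_hazard *
    ifelse(affected[d], config$deficiency_hazard_ratio, 1)
  t_event <- stats::rexp(nd, rate = hazard)
  t_censor <- stats::runif(nd, config$censor_min, config$censor_max)
  surv <- tibble::tibble(
    participant_id = id[d],
    time_years = pmin(t_event, t_censor),
    event = t_event <= t_censor,
    age = round(stats::rnorm(nd, 58, 10), 1),
    sex = sex[d],
    smoking = stats::runif(nd) < 0.45,
    diabetes_duration = round(stats::runif(nd, 0, 10), 1),
    ldl = round(stats::rnorm(nd, 110, 30), 1),
    hypertension = stats::runif(nd) < 0.55
  )

  structure(
    list(participants = participants, draws = draws, genotypes = genotypes,
         survival = surv, config = config),
    class = "g6pd_cohort"
  )
}

empty_cohort <- function(config) {
  structure(
    list(
      participants = tibble::tibble(
        participant_id = character(), sex = character(),
        diabetes_flag = logical(), g6pd_dx_flag = logical(),
        cohort_label = character()
      ),
      draws = tibble::tibble(
        participant_id = character(), draw_date = as.Date(character()),
        glucose = numeric(), hba1c = numeric(), rdw = numeric()
      ),
      genotypes = tibble::tibble(
        participant_id = character(), sex = character(), allele_count = integer()
      ),
      survival = tibble::tibble(
        participant_id = character(), time_years = numeric(), event = logical(),
        age = numeric(), sex = character(), smoking = logical(),
        diabetes_duration = numeric(), ldl = numeric(), hypertension = logical()
      ),
      config = config
    ),
    class = "g6pd_cohort"
  )
}

#' Write a synthetic cohort to a fixture directory
#'
#' Emits `participants.csv`, `labs.csv`, `genotypes.csv`, an equivalent
#' single-variant VCF (`genotypes.vcf`), `survival.csv`, and a
#' `manifest.yaml` recording the full generator configuration including the
#' seed. Output is byte-deterministic given the bundle.
#'
#' @param bundle A `g6pd_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_fixture <- function(bundle, dir) {
  if (!inherits(bundle, "g6pd_cohort")) {
    abort_invalid("`bundle` must come from `generate_cohort()`.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    participants = file.path(dir, "participants.csv"),
    labs = file.path(dir, "labs.csv"),
    genotypes = file.path(dir, "genotypes.csv"),
    vcf = file.path(dir, "genotypes.vcf"),
    survival = file.path(dir, "survival.csv"),
    manifest = file.path(dir, "manifest.yaml")
  )
  readr::write_csv(bundle$participants, paths[["participants"]])
  readr::write_csv(bundle$draws, paths[["labs"]])
  readr::write_csv(bundle$genotypes, paths[["genotypes"]])
  writeLines(fixture_vcf_lines(bundle$genotypes), paths[["vcf"]])
  readr::write_csv(bundle$survival, paths[["survival"]])
  manifest <- unclass(bundle$config)
  yaml::write_yaml(list(generator = "g6pdscreen synthetic cohort",
                        config = manifest), paths[["manifest"]])
  invisible(paths)
}

# Single-variant VCF slice for rs1050828 (chrX, C>T). Males are written as
# haploid calls, females as diploid, matching the X dialect the reader
# accepts.
fixture_vcf_lines <- function(genotypes) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=X>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$participant_id), collapse = "\t")
  )
  if (nrow(genotypes) == 0L) {
    return(header)
  }
  gt <- ifelse(
    genotypes$sex == "male",
    as.character(genotypes$allele_count),
    c("0/0", "0/1", "1/1")[genotypes$allele_count + 1L]
  )
  record <- paste(c("X", "154536002", "rs1050828", "C", "T", ".", "PASS", ".",
                    "GT", gt), collapse = "\t")
  c(header, record)
}
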