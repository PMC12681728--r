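# Cohort construction: draw eligibility filtering, index-draw selection, and
# assembly of one analysis row per participant with an exclusion ledger.

#' Filter blood draws to those eligible for index-draw selection
#'
#' Draws with any missing or non-positive analyte (glucose, HbA1c, RDW) are
#' dropped first and counted. When fasting is not assured, draws with blood
#' glucose below 70 mg/dL or above 200 mg/dL are then excluded — the glucose
#' range heuristic for clinical draws of unknown fasting state; the bounds
#' themselves are retained (exclusion is strict). When `fasting_assured =
#' TRUE` (research cohorts where participants were asked to fast) the range
#' filter is bypassed.
#'
#' @param draws Tibble of blood draws with columns `participant_id`,
#'   `draw_date`, `glucose`, `hba1c`, `rdw`.
#' @param fasting_assured Logical; bypass the 70-200 mg/dL range filter.
#' @return The eligible draws, with a `draw_ledger` attribute counting
#'   `input`, `missing_or_invalid`, `glucose_out_of_range`, and `retained`
#'   draws.
#' @export
filter_eligible_draws <- function(draws, fasting_assured = FALSE) {
  validate_columns(draws, c("participant_id", "draw_date", "glucose", "hba1c", "rdw"),
                   "draw table")
  n_input <- nrow(draws)
  ok <- rep(TRUE, n_input)
  for (col in c("glucose", "hba1c", "rdw")) {
    v <- draws[[col]]
    ok <- ok & !is.na(v) & is.finite(v) & v > 0
  }
  complete <- draws[ok, , drop = FALSE]
  n_missing <- n_input - nrow(complete)
  if (isTRUE(fasting_assured)) {
    eligible <- complete
    n_range <- 0L
  } else {
    in_range <- complete$glucose >= 70 & complete$glucose <= 200
    eligible <- complete[in_range, , drop = FALSE]
    n_range <- nrow(complete) - nrow(eligible)
  }
  attr(eligible, "draw_ledger") <- c(
    input = n_input,
    missing_or_invalid = n_missing,
    glucose_out_of_range = n_range,
    retained = nrow(eligible)
  )
  eligible
}

#' Select the index draw for one participant
#'
#' Among a participant's eligible draws, the draw with the lowest blood
#' glucose is taken as the index draw — the draw most likely to have been
#' fasting. Ties on glucose are broken by earliest draw date, then by row
#' order, so selection is deterministic.
#'
#' @param eligible Tibble of eligible draws for a single participant.
#' @return A one-row tibble (the index draw).
#' @export
select_index_draw <- function(eligible) {
  if (nrow(eligible) == 0L) {
    rlang::abort("no eligible draws to select from.", class = "g6pd_no_eligible_draw")
  }
  if (length(unique(eligible$participant_id)) > 1L) {
    abort_integrity("`select_index_draw()` expects draws from a single participant.")
  }
  ord <- order(eligible$glucose, eligible$draw_date, seq_len(nrow(eligible)))
  eligible[ord[1L], , drop = FALSE]
}

#' Build the analysis table: one row per participant
#'
#' Applies [filter_eligible_draws()] and per-participant index-draw selection,
#' joins genotypes, and computes the glucose gap at the index draw. Emits one
#' analysis row per participant who has a genotype and at least one eligible
#' draw, together with an exclusion ledger whose participant counts
#' (`retained`, `no_genotype`, `no_eligible_draw`) sum to the number of input
#' participants.
#'
#' @param participants Tibble with `participant_id`, `sex`, and optional
#'   phenotype columns (`diabetes_flag`, `g6pd_dx_flag`, `cohort_label`)
#'   carried through to the output. Participant ids must be unique.
#' @param draws Draw table as in [filter_eligible_draws()].
#' @param genotypes Tibble with `participant_id` and `allele_count`.
#' @param fasting_assured Passed to [filter_eligible_draws()].
#' @return A tibble of analysis rows with attributes `exclusion_ledger`
#'   (participant-level, see [exclusion_ledger()]) and `draw_ledger`.
#' @export
build_cohort <- function(participants, draws, genotypes, fasting_assured = FALSE) {
  validate_columns(participants, c("participant_id", "sex"), "participant table")
  validate_columns(genotypes, c("participant_id", "allele_count"), "genotype table")
  if (anyDuplicated(participants$participant_id)) {
    abort_integrity("duplicate participant ids in the participant table.")
  }
  if (anyDuplicated(genotypes$participant_id)) {
    abort_integrity("duplicate participant ids in the genotype table.")
  }

  eligible <- filter_eligible_draws(draws, fasting_assured = fasting_assured)
  index <- eligible |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::arrange(.data$participant_id, .data$glucose, .data$draw_date, .data$.row) |>
    dplyr::distinct(.data$participant_id, .keep_all = TRUE) |>
    dplyr::select(-".row")

  genotyped <- dplyr::semi_join(participants, genotypes, by = "participant_id")
  no_genotype <- nrow(participants) - nrow(genotyped)

  rows <- genotyped |>
    dplyr::inner_join(index, by = "participant_id") |>
    dplyr::inner_join(
      dplyr::select(genotypes, "participant_id", "allele_count"),
      by = "participant_id"
    )
  no_eligible_draw <- nrow(genotyped) - nrow(rows)

  rows$zygosity <- zygosity_from_allele_count(rows$sex, rows$allele_count)
  rows$glucose_gap <- glucose_gap(rows$glucose, rows$hba1c)

  front <- c("participant_id", "sex", "allele_count", "zygosity",
             "draw_date", "glucose", "hba1c", "rdw", "glucose_gap")
  rows <- dplyr::select(rows, dplyr::all_of(front),
                        dplyr::any_of(c("diabetes_flag", "g6pd_dx_flag", "cohort_label")))

  ledger <- tibble::tibble(
    reason = c("retained", "no_genotype", "no_eligible_draw"),
    n = c(nrow(rows), no_genotype, no_eligible_draw)
  )
  attr(rows, "exclusion_ledger") <- ledger
  attr(rows, "draw_ledger") <- attr(eligible, "draw_ledger")
  rows
}

#' Participant-level exclusion ledger of a built cohort
#'
#' @param cohort An analysis table from [build_cohort()].
#' @return Tibble with columns `reason` and `n`; the counts sum to the number
#'   of input participants.
#' @export
exclusion_ledger <- function(cohort) {
  ledger <- attr(cohort, "exclusion_ledger")
  if (is.null(ledger)) {
    abort_invalid("`cohort` carries no exclusion ledger; was it built by `build_cohort()`?")
  }
  ledger
}
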