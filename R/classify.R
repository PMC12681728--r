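# The possible/likely deficiency decision rule.

#' Decision criteria for possible/likely G6PD deficiency
#'
#' Bundles the two published operating thresholds: RDW at or below
#' `rdw_threshold` (default 12) and glucose gap at or above `gg_threshold`
#' (default -15 mg/dL). "Possible" deficiency is the inclusive OR of the two
#' criteria (screening-oriented: high recall, lower precision); "likely"
#' deficiency is their AND (enrichment-oriented), so every likely-positive is
#' also possible-positive. Both comparisons are inclusive at the boundary.
#'
#' @param rdw_threshold RDW threshold (RDW units; applied as `rdw <= threshold`).
#' @param gg_threshold Glucose-gap threshold (mg/dL; applied as `gg >= threshold`).
#' @return An object of class `decision_criteria`.
#' @examples
#' decision_criteria()
#' decision_criteria(rdw_threshold = 12.5, gg_threshold = -18)
#' @export
decision_criteria <- function(rdw_threshold = 12, gg_threshold = -15) {
  check_numeric_finite(rdw_threshold, "rdw_threshold")
  check_numeric_finite(gg_threshold, "gg_threshold")
  if (length(rdw_threshold) != 1L || length(gg_threshold) != 1L) {
    abort_invalid("thresholds must be single numbers.")
  }
  structure(
    list(rdw_threshold = rdw_threshold, gg_threshold = gg_threshold),
    class = "decision_criteria"
  )
}

#' @export
print.decision_criteria <- function(x, ...) {
  cat(sprintf(
    "G6PD deficiency decision criteria\n  possible: RDW <= %g OR glucose gap >= %g mg/dL\n  likely:   RDW <= %g AND glucose gap >= %g mg/dL\n",
    x$rdw_threshold, x$gg_threshold, x$rdw_threshold, x$gg_threshold
  ))
  invisible(x)
}

#' Apply the possible/likely deficiency rule
#'
#' Evaluates the decision rule on vectors of RDW and glucose gap:
#' `possible = (rdw <= t_rdw) | (gg >= t_gg)` and
#' `likely = (rdw <= t_rdw) & (gg >= t_gg)`. By construction `likely`
#' implies `possible` for every input.
#'
#' @param rdw Numeric vector of RDW values.
#' @param gg Numeric vector of glucose gaps (mg/dL).
#' @param criteria A [decision_criteria()] object.
#' @return Tibble with logical columns `possible` and `likely`.
#' @examples
#' classify_deficiency(c(11, 14), c(-30, -10))
#' @export
classify_deficiency <- function(rdw, gg, criteria = decision_criteria()) {
  check_numeric_finite(rdw, "rdw")
  check_numeric_finite(gg, "gg")
  if (length(rdw) != length(gg)) {
    abort_invalid("`rdw` and `gg` must have matching lengths.")
  }
  rdw_low <- rdw <= criteria$rdw_threshold
  gg_high <- gg >= criteria$gg_threshold
  tibble::tibble(possible = rdw_low | gg_high, likely = rdw_low & gg_high)
}

#' Screen an analysis table
#'
#' Applies [classify_deficiency()] to the `rdw` and `glucose_gap` columns of
#' an analysis table from [build_cohort()].
#'
#' @param cohort Analysis table with `participant_id`, `rdw`, `glucose_gap`.
#' @inheritParams classify_deficiency
#' @return Tibble with `participant_id`, `possible`, `likely`.
#' @export
screen_cohort <- function(cohort, criteria = decision_criteria()) {
  validate_columns(cohort, c("participant_id", "rdw", "glucose_gap"), "analysis table")
  res <- classify_deficiency(cohort$rdw, cohort$glucose_gap, criteria)
  tibble::tibble(participant_id = cohort$participant_id,
                 possible = res$possible, likely = res$likely)
}
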