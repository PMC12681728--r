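# Glycemic discordance metrics: estimated average glucose, the glucose gap,
# and the fasting-glucose / HbA1c ratio comparator.

#' Estimated average glucose from HbA1c
#'
#' Maps glycated hemoglobin (NGSP %) to an estimated average glucose (eAG) in
#' mg/dL by the linear regression of mean glucose on HbA1c,
#' \deqn{eAG = 28.7 \times HbA1c - 46.7.}
#' The affine form is applied exactly, with no clamping or rounding, so that
#' the glucose gap decomposition `glucose_gap() + estimated_average_glucose()
#' == glucose` holds to machine precision. Units are fixed: HbA1c in NGSP
#' percent, glucose in mg/dL; inputs in IFCC mmol/mol or mmol/L must be
#' converted beforehand.
#'
#' @param hba1c Numeric vector of HbA1c values (%, NGSP). Must be finite and
#'   strictly positive.
#' @return Numeric vector of estimated average glucose values (mg/dL).
#' @examples
#' estimated_average_glucose(5.6)
#' estimated_average_glucose(c(5.0, 6.0, 7.0))
#' @seealso [glucose_gap()], [chang_ratio()]
#' @export
estimated_average_glucose <- function(hba1c) {
  check_hba1c(hba1c)
  28.7 * hba1c - 46.7
}

#' Glucose gap: measured glucose minus HbA1c-estimated glucose
#'
#' The glucose gap (GG) is measured blood glucose minus the estimated average
#' glucose implied by HbA1c ([estimated_average_glucose()]). In carriers of
#' red-cell disorders that shorten erythrocyte lifespan (such as G6PD
#' deficiency), HbA1c under-reports true glycemia, shifting the gap upward;
#' a gap at or above -15 mg/dL is one arm of the screening rule applied by
#' [classify_deficiency()].
#'
#' @param glucose Numeric vector of blood glucose values (mg/dL), finite and
#'   non-negative.
#' @inheritParams estimated_average_glucose
#' @return Numeric vector of glucose gaps (mg/dL). No rounding is applied.
#' @examples
#' glucose_gap(88, 5.6) # about -26 mg/dL
#' @export
glucose_gap <- function(glucose, hba1c) {
  check_glucose(glucose)
  glucose - estimated_average_glucose(hba1c)
}

#' Fasting glucose to HbA1c ratio
#'
#' The glucose/HbA1c ratio, an earlier published laboratory comparator for
#' G6PD-deficiency screening. Provided for head-to-head evaluation against
#' the glucose gap; higher ratios indicate glucose in excess of what HbA1c
#' suggests.
#'
#' @inheritParams glucose_gap
#' @return Numeric vector of ratios (mg/dL per HbA1c %).
#' @examples
#' chang_ratio(100, 5.0)
#' @export
chang_ratio <- function(glucose, hba1c) {
  check_glucose(glucose)
  check_hba1c(hba1c)
  glucose / hba1c
}

check_hba1c <- function(hba1c) {
  if (!is.numeric(hba1c) || length(hba1c) == 0L || anyNA(hba1c) ||
      any(!is.finite(hba1c)) || any(hba1c <= 0)) {
    abort_invalid("`hba1c` must be finite and strictly positive (%, NGSP).")
  }
  invisible(hba1c)
}

check_glucose <- function(glucose) {
  if (!is.numeric(glucose) || length(glucose) == 0L || anyNA(glucose) ||
      any(!is.finite(glucose)) || any(glucose < 0)) {
    abort_invalid("`glucose` must be finite and non-negative (mg/dL).")
  }
  invisible(glucose)
}
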