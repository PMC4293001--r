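#' The AML maintained-group survival data
#'
#' Eleven observations from the classic acute myelogenous leukemia (AML)
#' maintenance-chemotherapy trial, maintained arm: time to relapse in weeks
#' and an event indicator (1 = relapse observed, 0 = censored).  This tiny,
#' widely reproduced dataset is the canonical worked example for risk-set
#' recovery: its Kaplan-Meier curve has seven jumps and three visible
#' censoring marks, plus one censoring hidden at an event time ("13+").
#'
#' @return A tibble with columns `time` (weeks) and `status` (1 event,
#'   0 censored), one row per subject.
#' @examples
#' aml_maintained()
#' km_curve(aml_maintained())
#' @export
aml_maintained <- function() {
  tibble::tibble(
    time   = c(9, 13, 13, 18, 23, 28, 31, 34, 45, 48, 161),
    status = c(1, 1, 0, 1, 1, 0, 1, 1, 0, 1, 0)
  )
}
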