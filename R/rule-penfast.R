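PENFAST_POINTS <- c(F = 2L, A = 2L, S = 2L, T = 1L)
PENFAST_CUTOFF <- 3L

#' Score patient histories with the PEN-FAST decision rule
#'
#' PEN-FAST is a bedside point score for reported penicillin allergy. The
#' PEN gate (an allergy is reported at all) is assumed satisfied for every
#' record in a suspected-reaction cohort; the four scored items are:
#'
#' * **F** — five years or less since the reaction: 2 points;
#' * **A** — anaphylaxis or angioedema: 2 points;
#' * **S** — severe cutaneous adverse reaction: 2 points;
#' * **T** — treatment was required for the reaction: 1 point.
#'
#' A total below 3 classifies the case as low risk (eligible for
#' de-labelling). An undocumented item scores 0 points: the score is a
#' screen, and a feature that is not in the record cannot add risk; the
#' `known_items` count lets callers audit how much of each score rests on
#' documented answers.
#'
#' @param histories tibble of patient histories carrying the four
#'   `penfast_*` item fields.
#' @return tibble with columns `case_id`, `F`, `A`, `S`, `T` (awarded
#'   points), `known_items` (how many of the four items were documented),
#'   `total` (0-7) and `low_risk` (`total < 3`).
#' @examples
#' h <- patient_history("p1",
#'   penfast_five_years_or_less = TRUE,
#'   penfast_anaphylaxis_or_angioedema = TRUE,
#'   penfast_severe_cutaneous = FALSE,
#'   penfast_treatment_required = FALSE
#' )
#' pen_fast(h) # total 4, not low risk
#' @export
pen_fast <- function(histories) {
  validate_histories(histories)
  item <- function(x, pts) ifelse(!is.na(x) & x, pts, 0L)
  f <- item(histories$penfast_five_years_or_less, PENFAST_POINTS[["F"]])
  a <- item(histories$penfast_anaphylaxis_or_angioedema, PENFAST_POINTS[["A"]])
  s <- item(histories$penfast_severe_cutaneous, PENFAST_POINTS[["S"]])
  t <- item(histories$penfast_treatment_required, PENFAST_POINTS[["T"]])
  known <- (!is.na(histories$penfast_five_years_or_less)) +
    (!is.na(histories$penfast_anaphylaxis_or_angioedema)) +
    (!is.na(histories$penfast_severe_cutaneous)) +
    (!is.na(histories$penfast_treatment_required))
  total <- f + a + s + t
  tibble::tibble(
    case_id = histories$case_id,
    F = as.integer(f), A = as.integer(a), S = as.integer(s), T = as.integer(t),
    known_items = as.integer(known),
    total = as.integer(total),
    low_risk = total < PENFAST_CUTOFF
  )
}
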