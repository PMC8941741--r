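QUESTIONS <- c("Q1", "Q2", "Q3", "Q4", "Q5")

#' Evaluate a single algorithm question on patient histories
#'
#' Answers one of the five key questions from the structured history fields,
#' vectorized over rows. Tri-state semantics: a question answers `yes` only
#' when its driving condition is positively documented, `no` only when the
#' driving fields are documented and negative, and `uncertain` otherwise —
#' so missing information can never produce a definitive answer.
#'
#' The questions:
#' * **Q1** — complaints incompatible with allergy (isolated abdominal pain,
#'   palpitation, headache and similar pharmacological side effects), or
#'   onset clearly too late for an allergic reaction (urticaria more than
#'   2 days, exanthema more than 1 week after last intake).
#' * **Q2** — urticarial or exanthematous rash in childhood or adolescence
#'   without systemic symptoms (almost always infection-related, not
#'   allergy). An age at reaction at or above `adult_threshold` overrides a
#'   `yes` on the rash field.
#' * **Q3** — prolonged urticaria episode(s) without respiratory or
#'   cardiovascular involvement, including recurrence days after stopping
#'   treatment.
#' * **Q4** — measles-like (maculopapular) exanthema in timely relation to
#'   intake, arising in adulthood.
#' * **Q5** — any documented indicator of a severe drug reaction: onset
#'   within minutes, cardiovascular or respiratory signs, an incident
#'   during general anesthesia, mucosal erosions, cutaneous blisters,
#'   hepatitis, nephritis, or a sudden drop of blood cell numbers. An empty
#'   indicator set answers `no`.
#'
#' @param question one of `"Q1"` .. `"Q5"`.
#' @param histories tibble of patient histories (validated).
#' @param adult_threshold age in years at and above which a reaction counts
#'   as adult (default 18).
#' @return character vector of tri-state answers, one per row.
#' @export
evaluate_question <- function(question, histories, adult_threshold = 18) {
  if (!(is.character(question) && length(question) == 1 &&
        question %in% QUESTIONS)) {
    abort_delabel(sprintf("unknown question code '%s'; use Q1..Q5",
                          paste(question, collapse = ",")),
                  "delabelr_usage_error")
  }
  validate_histories(histories)
  h <- histories
  switch(question,
    Q1 = {
      late <- h$onset_latency %in% c("days_urticaria_gt2", "weeks_exanthema_gt1")
      yes <- h$symptoms_incompatible_with_allergy == "yes" | late
      no <- h$symptoms_incompatible_with_allergy == "no" &
        h$onset_latency %in% c("minutes", "hours_to_days")
      ifelse(yes, "yes", ifelse(no, "no", "uncertain"))
    },
    Q2 = {
      age <- h$age_at_reaction_years
      adult <- !is.na(age) & age >= adult_threshold
      yes <- h$rash_in_childhood_no_systemic == "yes" & !adult
      no <- h$rash_in_childhood_no_systemic == "no" |
        (h$rash_in_childhood_no_systemic == "yes" & adult)
      ifelse(yes, "yes", ifelse(no, "no", "uncertain"))
    },
    Q3 = h$prolonged_urticaria_no_systemic,
    Q4 = h$measles_like_exanthema_adult,
    Q5 = {
      n_flags <- lengths(severe_flags_list(h$severe_indicators))
      ifelse(n_flags > 0, "yes", "no")
    }
  )
}

#' Apply the five-question de-labelling algorithm
#'
#' Runs questions Q1-Q4 in order, stopping at the first `yes`; any `no` or
#' `uncertain` answer routes onward, and cases reaching Q4 without a `yes`
#' are assessed for severe-reaction indicators at Q5. The outcome is binary:
#'
#' * `yes` at Q1, Q2 or Q3 — de-label (the reported reaction speaks against
#'   allergic hypersensitivity);
#' * `yes` at Q4 — use an alternative antibiotic (likely maculopapular
#'   exanthema on re-exposure, bothersome though not severe);
#' * Q5 `yes` — alternative antibiotic (potential severe reaction);
#'   Q5 `no` or `uncertain` — de-label. Resolving an uncertain Q5 toward
#'   de-labelling is the algorithm's residual-risk locus: no severe
#'   indicator is documented, so the case is treated as low risk.
#'
#' @param histories tibble of patient histories.
#' @param adult_threshold passed to [evaluate_question()] for Q2.
#' @return tibble of decisions: `case_id`, `recommendation` (`"de_label"` or
#'   `"alternative_antibiotic"`), `deciding_question`, and the answer trace
#'   in columns `Q1` .. `Q5` (`NA` for questions never reached).
#' @examples
#' h <- patient_history(c("a", "b"),
#'   measles_like_exanthema_adult = c("yes", "no"),
#'   age_at_reaction_years = c(35, 40)
#' )
#' apply_algorithm(h)
#' @export
apply_algorithm <- function(histories, adult_threshold = 18) {
  validate_histories(histories)
  n <- nrow(histories)
  if (n == 0) {
    out <- tibble::tibble(case_id = character(0),
                          recommendation = character(0),
                          deciding_question = character(0))
    for (q in QUESTIONS) out[[q]] <- character(0)
    return(out)
  }
  ans <- vapply(QUESTIONS, function(q) {
    evaluate_question(q, histories, adult_threshold)
  }, character(n))
  if (n == 1) ans <- matrix(ans, 1, 5, dimnames = list(NULL, QUESTIONS))
  first_yes <- apply(ans[, 1:4, drop = FALSE] == "yes", 1,
                     function(r) if (any(r)) which(r)[1] else 5L)
  deciding <- QUESTIONS[first_yes]
  recommendation <- ifelse(
    deciding %in% c("Q1", "Q2", "Q3"), "de_label",
    ifelse(deciding == "Q4", "alternative_antibiotic",
           ifelse(ans[, "Q5"] == "yes", "alternative_antibiotic", "de_label"))
  )
  trace <- ans
  for (j in seq_len(5)) {
    trace[first_yes < j, j] <- NA_character_
  }
  out <- tibble::tibble(
    case_id = histories$case_id,
    recommendation = as.character(recommendation),
    deciding_question = as.character(deciding)
  )
  for (q in QUESTIONS) out[[q]] <- as.character(trace[, q])
  out
}

#' Cross-tabulate decisions by deciding question, recommendation and truth
#'
#' Counts cases in every (deciding question, recommendation, allergic) cell,
#' over the complete grid including empty cells, so that the counts always
#' sum to the cohort size and marginalizing over the deciding question
#' recovers the 2x2 classification table.
#'
#' @param decisions tibble from [apply_algorithm()].
#' @param truths tibble of ground truth; `case_id`s must match the decisions
#'   one-to-one.
#' @return tibble with columns `deciding_question`, `recommendation`,
#'   `allergic`, `n`.
#' @export
route_counts <- function(decisions, truths) {
  match_cases(decisions$case_id, truths$case_id)
  allergic <- truths$allergic[match(decisions$case_id, truths$case_id)]
  tab <- table(
    deciding_question = factor(decisions$deciding_question, levels = QUESTIONS),
    recommendation = factor(decisions$recommendation,
                            levels = c("de_label", "alternative_antibiotic")),
    allergic = factor(allergic, levels = c(FALSE, TRUE))
  )
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out)[4] <- "n"
  out$allergic <- as.logical(out$allergic)
  tibble::as_tibble(out)
}

# internal: require a one-to-one case_id correspondence
match_cases <- function(ids_a, ids_b) {
  if (anyDuplicated(ids_a) || anyDuplicated(ids_b)) {
    abort_delabel("duplicate case_id", "delabelr_validation_error")
  }
  if (length(ids_a) != length(ids_b) || !setequal(ids_a, ids_b)) {
    off <- c(setdiff(ids_a, ids_b), setdiff(ids_b, ids_a))
    abort_delabel(sprintf("case_ids do not match one-to-one (e.g. '%s')",
                          if (length(off)) off[1] else ids_a[1]),
                  "delabelr_validation_error")
  }
  invisible(TRUE)
}
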