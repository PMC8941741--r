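# Shared builders for small hand-constructed cohorts.

# a history where every question driver is documented negative;
# named arguments in ... override the negatives
blank_history <- function(case_id = "c1", ...) {
  args <- list(
    case_id = case_id,
    symptoms_incompatible_with_allergy = "no",
    onset_latency = "hours_to_days",
    rash_in_childhood_no_systemic = "no",
    age_at_reaction_years = 40,
    prolonged_urticaria_no_systemic = "no",
    measles_like_exanthema_adult = "no",
    severe_indicators = ""
  )
  args[names(list(...))] <- list(...)
  do.call(patient_history, args)
}

# random valid histories for property-style tests; drivers drawn
# independently so all routing paths occur
random_histories <- function(n, seed) {
  set.seed(seed)
  patient_history(
    case_id = sprintf("r%04d", seq_len(n)),
    symptoms_incompatible_with_allergy = sample(TRI_STATE, n, TRUE),
    onset_latency = sample(ONSET_LATENCY, n, TRUE),
    rash_in_childhood_no_systemic = sample(TRI_STATE, n, TRUE),
    age_at_reaction_years = ifelse(runif(n) < 0.1, NA,
                                   sample(0:90, n, TRUE)),
    prolonged_urticaria_no_systemic = sample(TRI_STATE, n, TRUE),
    measles_like_exanthema_adult = sample(TRI_STATE, n, TRUE),
    severe_indicators = vapply(seq_len(n), function(i) {
      k <- sample(0:3, 1)
      paste(sample(SEVERE_INDICATORS, k), collapse = ";")
    }, character(1)),
    culprit_class = sample(CULPRIT_CLASS, n, TRUE),
    route = sample(ROUTE, n, TRUE),
    recall_interval = sample(RECALL_INTERVAL, n, TRUE),
    reported_type = sample(REPORTED_TYPE, n, TRUE),
    penfast_five_years_or_less = sample(c(TRUE, FALSE, NA), n, TRUE),
    penfast_anaphylaxis_or_angioedema = sample(c(TRUE, FALSE, NA), n, TRUE),
    penfast_severe_cutaneous = sample(c(TRUE, FALSE, NA), n, TRUE),
    penfast_treatment_required = sample(c(TRUE, FALSE, NA), n, TRUE)
  )
}

# random ground truth matching a set of case_ids
random_truths <- function(case_ids, seed) {
  set.seed(seed)
  n <- length(case_ids)
  allergic <- runif(n) < 0.3
  mech <- ifelse(allergic, sample(MECHANISM, n, TRUE), NA)
  ground_truth(
    case_id = case_ids,
    allergic = allergic,
    mechanism = mech,
    anaphylaxis_severity = ifelse(!is.na(mech) & mech == "immediate_anaphylaxis",
                                  sample(ANAPHYLAXIS_SEVERITY, n, TRUE), NA),
    delayed_subtype = ifelse(!is.na(mech) & mech == "delayed",
                             sample(DELAYED_SUBTYPE, n, TRUE), NA)
  )
}
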