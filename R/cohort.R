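#' Controlled vocabularies for patient-history records
#'
#' Constants defining the coded values a cohort may carry. Question-type
#' fields are tri-state (`"yes"`, `"no"`, `"uncertain"`): the de-labelling
#' algorithm routes `uncertain` identically to `no` at questions 1-4, so
#' absence of information never silently de-labels. The two late-onset
#' latency codes encode the question-1 thresholds: urticaria starting more
#' than 2 days, or exanthema more than 1 week, after the last intake.
#'
#' @name vocabularies
#' @keywords internal
NULL

#' @rdname vocabularies
#' @export
TRI_STATE <- c("yes", "no", "uncertain")

#' @rdname vocabularies
#' @export
ONSET_LATENCY <- c("minutes", "hours_to_days", "days_urticaria_gt2",
                   "weeks_exanthema_gt1", "unknown")

#' @rdname vocabularies
#' @export
SEVERE_INDICATORS <- c("onset_within_minutes", "cardiovascular_signs",
                       "respiratory_signs", "incident_during_anesthesia",
                       "mucosal_erosions", "cutaneous_blisters",
                       "hepatitis", "nephritis", "blood_cell_drop")

#' @rdname vocabularies
#' @export
CULPRIT_CLASS <- c("aminopenicillin", "cephalosporin",
                   "benzyl_phenoxymethyl_penicillin", "other", "unclear")

#' @rdname vocabularies
#' @export
ROUTE <- c("oral", "intravenous", "intramuscular", "unclear")

#' @rdname vocabularies
#' @export
RECALL_INTERVAL <- c("le_1y", "y1_5", "y5_10", "gt_10y", "unclear")

#' @rdname vocabularies
#' @export
REPORTED_TYPE <- c("immediate", "delayed", "uncertain")

#' @rdname vocabularies
#' @export
MECHANISM <- c("immediate_anaphylaxis", "delayed")

#' @rdname vocabularies
#' @export
ANAPHYLAXIS_SEVERITY <- c("mild", "moderate", "severe")

#' @rdname vocabularies
#' @export
DELAYED_SUBTYPE <- c("maculopapular_exanthema", "SDRIFE", "FDE", "DRESS")

history_columns <- c(
  "case_id", "symptoms_incompatible_with_allergy", "onset_latency",
  "rash_in_childhood_no_systemic", "age_at_reaction_years",
  "prolonged_urticaria_no_systemic", "measles_like_exanthema_adult",
  "severe_indicators", "culprit_class", "route", "recall_interval",
  "reported_type", "penfast_five_years_or_less",
  "penfast_anaphylaxis_or_angioedema", "penfast_severe_cutaneous",
  "penfast_treatment_required"
)

truth_columns <- c("case_id", "allergic", "mechanism",
                   "anaphylaxis_severity", "delayed_subtype")

#' Construct patient-history records
#'
#' Builds a tibble of suspected-reaction histories, one row per case, with
#' every field defaulting to its "no information" code (`uncertain` for
#' question inputs, `unknown`/`unclear`/`NA` for factual fields, empty set
#' for severe indicators). All arguments recycle to the length of `case_id`.
#'
#' @param case_id character vector of unique case identifiers.
#' @param symptoms_incompatible_with_allergy,rash_in_childhood_no_systemic,prolonged_urticaria_no_systemic,measles_like_exanthema_adult
#'   tri-state answers (`"yes"`, `"no"`, `"uncertain"`).
#' @param onset_latency coarse onset timing, one of [ONSET_LATENCY].
#' @param age_at_reaction_years age in years at the index reaction
#'   (0-120), `NA` if unknown.
#' @param severe_indicators severe-reaction flags per case: a character
#'   vector of semicolon-joined flag names from [SEVERE_INDICATORS]
#'   (`""` = none reported).
#' @param culprit_class,route,recall_interval,reported_type coded Table-style
#'   descriptors of the reported reaction; see [vocabularies].
#' @param penfast_five_years_or_less,penfast_anaphylaxis_or_angioedema,penfast_severe_cutaneous,penfast_treatment_required
#'   PEN-FAST item answers, logical (`NA` = undocumented).
#' @return tibble with one row per case and the full history schema.
#' @examples
#' patient_history("p1", measles_like_exanthema_adult = "yes",
#'                 age_at_reaction_years = 42)
#' @export
patient_history <- function(case_id,
                            symptoms_incompatible_with_allergy = "uncertain",
                            onset_latency = "unknown",
                            rash_in_childhood_no_systemic = "uncertain",
                            age_at_reaction_years = NA_real_,
                            prolonged_urticaria_no_systemic = "uncertain",
                            measles_like_exanthema_adult = "uncertain",
                            severe_indicators = "",
                            culprit_class = "unclear",
                            route = "unclear",
                            recall_interval = "unclear",
                            reported_type = "uncertain",
                            penfast_five_years_or_less = NA,
                            penfast_anaphylaxis_or_angioedema = NA,
                            penfast_severe_cutaneous = NA,
                            penfast_treatment_required = NA) {
  h <- tibble::tibble(
    case_id = as.character(case_id),
    symptoms_incompatible_with_allergy = as.character(symptoms_incompatible_with_allergy),
    onset_latency = as.character(onset_latency),
    rash_in_childhood_no_systemic = as.character(rash_in_childhood_no_systemic),
    age_at_reaction_years = as.numeric(age_at_reaction_years),
    prolonged_urticaria_no_systemic = as.character(prolonged_urticaria_no_systemic),
    measles_like_exanthema_adult = as.character(measles_like_exanthema_adult),
    severe_indicators = as.character(severe_indicators),
    culprit_class = as.character(culprit_class),
    route = as.character(route),
    recall_interval = as.character(recall_interval),
    reported_type = as.character(reported_type),
    penfast_five_years_or_less = as.logical(penfast_five_years_or_less),
    penfast_anaphylaxis_or_angioedema = as.logical(penfast_anaphylaxis_or_angioedema),
    penfast_severe_cutaneous = as.logical(penfast_severe_cutaneous),
    penfast_treatment_required = as.logical(penfast_treatment_required)
  )
  validate_histories(h)
  h
}

#' Construct ground-truth records
#'
#' One row per adjudicated case. `mechanism` is required exactly when
#' `allergic` is `TRUE`; `anaphylaxis_severity` accompanies an
#' immediate-type (anaphylaxis) diagnosis and `delayed_subtype` a
#' delayed-type diagnosis, never both.
#'
#' @param case_id character vector matching history `case_id`s.
#' @param allergic logical: beta-lactam hypersensitivity proven (`TRUE`) or
#'   excluded by negative challenge testing (`FALSE`).
#' @param mechanism `"immediate_anaphylaxis"` or `"delayed"` when allergic,
#'   else `NA`.
#' @param anaphylaxis_severity `"mild"`, `"moderate"` or `"severe"` for
#'   immediate-type cases, else `NA`.
#' @param delayed_subtype one of [DELAYED_SUBTYPE] for delayed-type cases,
#'   else `NA`.
#' @return tibble with the ground-truth schema.
#' @export
ground_truth <- function(case_id, allergic,
                         mechanism = NA_character_,
                         anaphylaxis_severity = NA_character_,
                         delayed_subtype = NA_character_) {
  g <- tibble::tibble(
    case_id = as.character(case_id),
    allergic = as.logical(allergic),
    mechanism = as.character(mechanism),
    anaphylaxis_severity = as.character(anaphylaxis_severity),
    delayed_subtype = as.character(delayed_subtype)
  )
  validate_truths(g)
  g
}

severe_flags_list <- function(severe_indicators) {
  x <- as.character(severe_indicators)
  x[is.na(x)] <- ""
  strsplit(x, ";", fixed = TRUE)
}

check_enum <- function(x, allowed, field, na_ok = FALSE) {
  bad <- if (na_ok) which(!is.na(x) & !(x %in% allowed)) else which(!(x %in% allowed))
  if (length(bad)) {
    abort_delabel(
      sprintf("invalid value '%s' for %s (row %d); allowed: %s",
              x[bad[1]], field, bad[1], paste(allowed, collapse = ", ")),
      "delabelr_validation_error"
    )
  }
}

#' Validate a tibble of patient histories
#'
#' Checks the schema, controlled vocabularies, case-id uniqueness, age
#' range, and the severe-indicator flag set. Called by every rule-facing
#' entry point; exported for use on externally assembled data.
#'
#' @param histories tibble with the [patient_history()] schema.
#' @return `histories`, invisibly, if valid; otherwise an error.
#' @export
validate_histories <- function(histories) {
  missing <- setdiff(history_columns, names(histories))
  if (length(missing)) {
    abort_delabel(paste0("missing mandatory column(s): ",
                         paste(missing, collapse = ", ")),
                  "delabelr_schema_error")
  }
  if (anyDuplicated(histories$case_id)) {
    dup <- histories$case_id[duplicated(histories$case_id)][1]
    abort_delabel(sprintf("duplicate case_id '%s'", dup),
                  "delabelr_validation_error")
  }
  for (f in c("symptoms_incompatible_with_allergy",
              "rash_in_childhood_no_systemic",
              "prolonged_urticaria_no_systemic",
              "measles_like_exanthema_adult")) {
    check_enum(histories[[f]], TRI_STATE, f)
  }
  check_enum(histories$onset_latency, ONSET_LATENCY, "onset_latency")
  check_enum(histories$culprit_class, CULPRIT_CLASS, "culprit_class")
  check_enum(histories$route, ROUTE, "route")
  check_enum(histories$recall_interval, RECALL_INTERVAL, "recall_interval")
  check_enum(histories$reported_type, REPORTED_TYPE, "reported_type")
  age <- histories$age_at_reaction_years
  bad_age <- which(!is.na(age) & (age < 0 | age > 120))
  if (length(bad_age)) {
    abort_delabel(sprintf("age_at_reaction_years out of [0, 120] (row %d)",
                          bad_age[1]),
                  "delabelr_validation_error")
  }
  flags <- severe_flags_list(histories$severe_indicators)
  bad_flag <- which(vapply(flags, function(f) any(!(f %in% SEVERE_INDICATORS)),
                           logical(1)))
  if (length(bad_flag)) {
    abort_delabel(sprintf("unknown severe indicator in row %d: '%s'",
                          bad_flag[1], histories$severe_indicators[bad_flag[1]]),
                  "delabelr_validation_error")
  }
  invisible(histories)
}

#' Validate a tibble of ground-truth adjudications
#'
#' Enforces the diagnostic structure: a mechanism exactly for allergic
#' cases, an anaphylaxis severity exactly for immediate-type cases, a
#' delayed subtype exactly for delayed-type cases.
#'
#' @param truths tibble with the [ground_truth()] schema.
#' @return `truths`, invisibly, if valid; otherwise an error.
#' @export
validate_truths <- function(truths) {
  missing <- setdiff(truth_columns, names(truths))
  if (length(missing)) {
    abort_delabel(paste0("missing mandatory column(s): ",
                         paste(missing, collapse = ", ")),
                  "delabelr_schema_error")
  }
  if (anyDuplicated(truths$case_id)) {
    abort_delabel(sprintf("duplicate case_id '%s'",
                          truths$case_id[duplicated(truths$case_id)][1]),
                  "delabelr_validation_error")
  }
  if (any(is.na(truths$allergic))) {
    abort_delabel("allergic must be TRUE or FALSE for every case",
                  "delabelr_validation_error")
  }
  check_enum(truths$mechanism, MECHANISM, "mechanism", na_ok = TRUE)
  check_enum(truths$anaphylaxis_severity, ANAPHYLAXIS_SEVERITY,
             "anaphylaxis_severity", na_ok = TRUE)
  check_enum(truths$delayed_subtype, DELAYED_SUBTYPE,
             "delayed_subtype", na_ok = TRUE)
  bad <- which(truths$allergic != !is.na(truths$mechanism))
  if (length(bad)) {
    abort_delabel(sprintf("mechanism must be present iff allergic (row %d)",
                          bad[1]),
                  "delabelr_validation_error")
  }
  imm <- !is.na(truths$mechanism) & truths$mechanism == "immediate_anaphylaxis"
  del <- !is.na(truths$mechanism) & truths$mechanism == "delayed"
  bad <- which((imm & (is.na(truths$anaphylaxis_severity) | !is.na(truths$delayed_subtype))) |
               (del & (is.na(truths$delayed_subtype) | !is.na(truths$anaphylaxis_severity))) |
               (!truths$allergic & (!is.na(truths$anaphylaxis_severity) | !is.na(truths$delayed_subtype))))
  if (length(bad)) {
    abort_delabel(
      sprintf("severity/subtype must match mechanism exclusively (row %d)", bad[1]),
      "delabelr_validation_error"
    )
  }
  invisible(truths)
}

# ---- serialization ---------------------------------------------------------

# map in-memory tibbles to the flat character form shared by CSV and JSON
histories_to_flat <- function(h) {
  data.frame(
    case_id = h$case_id,
    symptoms_incompatible_with_allergy = h$symptoms_incompatible_with_allergy,
    onset_latency = h$onset_latency,
    rash_in_childhood_no_systemic = h$rash_in_childhood_no_systemic,
    age_at_reaction_years = ifelse(is.na(h$age_at_reaction_years), "",
                                   format(h$age_at_reaction_years, trim = TRUE,
                                          scientific = FALSE)),
    prolonged_urticaria_no_systemic = h$prolonged_urticaria_no_systemic,
    measles_like_exanthema_adult = h$measles_like_exanthema_adult,
    severe_indicators = h$severe_indicators,
    culprit_class = h$culprit_class,
    route = h$route,
    recall_interval = h$recall_interval,
    reported_type = h$reported_type,
    penfast_five_years_or_less = logical_to_flat(h$penfast_five_years_or_less),
    penfast_anaphylaxis_or_angioedema = logical_to_flat(h$penfast_anaphylaxis_or_angioedema),
    penfast_severe_cutaneous = logical_to_flat(h$penfast_severe_cutaneous),
    penfast_treatment_required = logical_to_flat(h$penfast_treatment_required),
    stringsAsFactors = FALSE, check.names = FALSE
  )
}

truths_to_flat <- function(g) {
  data.frame(
    allergic = ifelse(g$allergic, "true", "false"),
    mechanism = ifelse(is.na(g$mechanism), "", g$mechanism),
    anaphylaxis_severity = ifelse(is.na(g$anaphylaxis_severity), "",
                                  g$anaphylaxis_severity),
    delayed_subtype = ifelse(is.na(g$delayed_subtype), "", g$delayed_subtype),
    stringsAsFactors = FALSE, check.names = FALSE
  )
}

logical_to_flat <- function(x) ifelse(is.na(x), "", ifelse(x, "true", "false"))

flat_to_logical <- function(x, field) {
  x <- trimws(x)
  out <- rep(NA, length(x))
  out[x %in% c("true", "TRUE", "True")] <- TRUE
  out[x %in% c("false", "FALSE", "False")] <- FALSE
  bad <- which(!(x %in% c("", "true", "TRUE", "True", "false", "FALSE", "False", "NA")))
  if (length(bad)) {
    abort_delabel(sprintf("unparseable boolean '%s' for %s (row %d)",
                          x[bad[1]], field, bad[1]),
                  "delabelr_validation_error")
  }
  out
}

# blank cells carry no information: question inputs read as "uncertain",
# factual codes as their respective unknown code, numerics as NA
flat_to_histories <- function(d) {
  blank_to <- function(x, code) {
    x <- trimws(as.character(x))
    x[is.na(x) | x == ""] <- code
    x
  }
  age_raw <- trimws(as.character(d$age_at_reaction_years))
  age <- suppressWarnings(as.numeric(age_raw))
  bad <- which(!(age_raw %in% c("", "NA")) & is.na(age))
  if (length(bad)) {
    abort_delabel(sprintf("unparseable age_at_reaction_years '%s' (row %d)",
                          age_raw[bad[1]], bad[1]),
                  "delabelr_validation_error")
  }
  tibble::tibble(
    case_id = as.character(d$case_id),
    symptoms_incompatible_with_allergy = blank_to(d$symptoms_incompatible_with_allergy, "uncertain"),
    onset_latency = blank_to(d$onset_latency, "unknown"),
    rash_in_childhood_no_systemic = blank_to(d$rash_in_childhood_no_systemic, "uncertain"),
    age_at_reaction_years = age,
    prolonged_urticaria_no_systemic = blank_to(d$prolonged_urticaria_no_systemic, "uncertain"),
    measles_like_exanthema_adult = blank_to(d$measles_like_exanthema_adult, "uncertain"),
    severe_indicators = blank_to(d$severe_indicators, ""),
    culprit_class = blank_to(d$culprit_class, "unclear"),
    route = blank_to(d$route, "unclear"),
    recall_interval = blank_to(d$recall_interval, "unclear"),
    reported_type = blank_to(d$reported_type, "uncertain"),
    penfast_five_years_or_less = flat_to_logical(d$penfast_five_years_or_less, "penfast_five_years_or_less"),
    penfast_anaphylaxis_or_angioedema = flat_to_logical(d$penfast_anaphylaxis_or_angioedema, "penfast_anaphylaxis_or_angioedema"),
    penfast_severe_cutaneous = flat_to_logical(d$penfast_severe_cutaneous, "penfast_severe_cutaneous"),
    penfast_treatment_required = flat_to_logical(d$penfast_treatment_required, "penfast_treatment_required")
  )
}

flat_to_truths <- function(d) {
  blank_na <- function(x) {
    x <- trimws(as.character(x))
    x[x == ""] <- NA_character_
    x
  }
  allergic_raw <- trimws(as.character(d$allergic))
  bad <- which(!(allergic_raw %in% c("true", "false", "TRUE", "FALSE")))
  if (length(bad)) {
    abort_delabel(sprintf("allergic must be true/false, got '%s' (row %d)",
                          allergic_raw[bad[1]], bad[1]),
                  "delabelr_validation_error")
  }
  tibble::tibble(
    case_id = as.character(d$case_id),
    allergic = tolower(allergic_raw) == "true",
    mechanism = blank_na(d$mechanism),
    anaphylaxis_severity = blank_na(d$anaphylaxis_severity),
    delayed_subtype = blank_na(d$delayed_subtype)
  )
}

guess_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("csv", "json")))
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
}

#' Read a cohort file
#'
#' Reads patient histories — and, when the ground-truth columns are present,
#' adjudicated diagnoses — from a CSV or JSON cohort file. Blank cells map
#' to the no-information codes (`uncertain` for question inputs, `unknown` /
#' `unclear` for factual fields, `NA` for age and PEN-FAST items). Both
#' parts are validated on read; record order is preserved.
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`; inferred from the file extension when
#'   `NULL`.
#' @return list with elements `histories` (tibble) and `truths` (tibble, or
#'   `NULL` when the file carries no ground-truth columns).
#' @seealso [write_cohort()] for the inverse; the two are lossless
#'   round-trip partners.
#' @export
read_cohort <- function(path, format = NULL) {
  format <- guess_format(path, format)
  if (!file.exists(path)) {
    abort_delabel(sprintf("file not found: %s", path), "delabelr_io_error")
  }
  d <- if (format == "csv") {
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    fileEncoding = "UTF-8")
  } else {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(raw) == 0) raw <- data.frame()
    as.data.frame(lapply(raw, as.character), stringsAsFactors = FALSE,
                  check.names = FALSE)
  }
  if (nrow(d) == 0 && length(names(d)) == 0) {
    # header-only JSON (empty array) carries the implicit full schema
    d <- as.data.frame(setNames(rep(list(character(0)), length(history_columns)),
                                history_columns), check.names = FALSE)
  }
  missing <- setdiff(history_columns, names(d))
  if (length(missing)) {
    abort_delabel(paste0("missing mandatory column(s): ",
                         paste(missing, collapse = ", ")),
                  "delabelr_schema_error")
  }
  histories <- flat_to_histories(d)
  validate_histories(histories)
  truths <- NULL
  if (any(truth_columns[-1] %in% names(d))) {
    missing_t <- setdiff(truth_columns[-1], names(d))
    if (length(missing_t)) {
      abort_delabel(paste0("incomplete ground-truth column(s); missing: ",
                           paste(missing_t, collapse = ", ")),
                    "delabelr_schema_error")
    }
    truths <- flat_to_truths(cbind(case_id = d$case_id, d[truth_columns[-1]]))
    validate_truths(truths)
  }
  list(histories = histories, truths = truths)
}

#' Write a cohort file
#'
#' Serializes histories (and optionally ground truth, merged by `case_id`
#' into the same table) to CSV or JSON. `NA`/unknown values write as empty
#' cells; `read_cohort()` of the result reproduces the input exactly.
#'
#' @param histories tibble of patient histories.
#' @param truths optional tibble of ground truth; every `case_id` must match
#'   a history row.
#' @param path output file path.
#' @param format `"csv"` or `"json"`; inferred from the extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(histories, truths = NULL, path, format = NULL) {
  format <- guess_format(path, format)
  validate_histories(histories)
  flat <- histories_to_flat(histories)
  if (!is.null(truths) && nrow(truths) > 0) {
    validate_truths(truths)
    unmatched <- setdiff(truths$case_id, histories$case_id)
    if (length(unmatched)) {
      abort_delabel(sprintf("ground truth references unknown case_id '%s'",
                            unmatched[1]),
                    "delabelr_validation_error")
    }
    tf <- truths_to_flat(truths)
    idx <- match(flat$case_id, truths$case_id)
    if (any(is.na(idx))) {
      abort_delabel(sprintf("no ground truth for case_id '%s'",
                            flat$case_id[which(is.na(idx))[1]]),
                    "delabelr_validation_error")
    }
    flat <- cbind(flat, tf[idx, , drop = FALSE])
  }
  if (format == "csv") {
    utils::write.csv(flat, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(flat, path, dataframe = "rows", pretty = TRUE)
  }
  invisible(path)
}
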