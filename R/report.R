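## Expected outcome structure of the study cohort, used by the
## self-verification harness to diff recomputed results against the
## published counts and percentages.
expected_results <- function() {
  list(
    two_by_two = c(tp = 184L, fp = 265L, fn = 21L, tn = 330L),
    headline = c(sensitivity = "89.8", specificity = "55.5",
                 ppv = "41.0", npv = "94.0"),
    routing_non_allergic = c(Q1 = 68L, Q2 = 66L, Q3 = 95L),
    routing_allergic_delabel = c(Q1 = 3L, Q2 = 2L, Q3 = 6L, Q5 = 10L),
    routing_q4 = c(non_allergic = 195L, allergic = 106L),
    routing_q5_alternative = c(non_allergic = 70L, allergic = 78L),
    strata = list(
      anaphylaxis = c(de_labelled = 8L, referred = 62L),
      mild = c(de_labelled = 7L, referred = 19L),
      moderate = c(de_labelled = 1L, referred = 26L),
      severe = c(de_labelled = 0L, referred = 17L),
      moderate_severe = c(de_labelled = 1L, referred = 43L),
      delayed = c(de_labelled = 13L, referred = 122L),
      maculopapular_exanthema = c(de_labelled = 11L, referred = 106L),
      SDRIFE = c(de_labelled = 2L, referred = 10L),
      FDE = c(de_labelled = 0L, referred = 3L),
      DRESS = c(de_labelled = 0L, referred = 3L)
    ),
    penfast_adjusted = c(ppv = "25.3", npv = "96.3"),
    penfast_inputs = c(sensitivity = 0.707, specificity = 0.785,
                       prevalence = 58 / 622)
  )
}

#' Render the stratified outcome table
#'
#' Formats an [stratified_report()] result in the layout of the published
#' comparison table: one row per ground-truth category with de-labelled
#' and referred counts (percentages on the two top-level rows) and the row
#' total. Missing strata render as absent with a warning.
#'
#' @param report an `accuracy_report` with a populated `strata` tree.
#' @return character vector of table lines (also usable via `cat`).
#' @export
render_table2 <- function(report) {
  s <- report$strata
  fmt <- function(label, leaf, pct = FALSE, indent = 1) {
    if (is.null(leaf) || is.null(leaf$total)) {
      warning("stratum '", label, "' absent from report", call. = FALSE)
      return(NULL)
    }
    pad <- strrep(" ", indent)
    if (pct) {
      sprintf("%s%s  %d (%s%%)  %d (%s%%)  %d", pad, label,
              leaf$de_labelled, percent1(leaf$de_labelled / leaf$total),
              leaf$referred, percent1(leaf$referred_prop), leaf$total)
    } else {
      sprintf("%s%s  %d  %d  %d", pad, label,
              leaf$de_labelled, leaf$referred, leaf$total)
    }
  }
  lines <- c(
    "Allergy testing  De-labelling  Use alternative antibiotic  Sum",
    fmt("Beta-lactam hypersensitivity excluded", s$non_allergic, pct = TRUE, indent = 0),
    fmt("Allergic beta-lactam hypersensitivity proven (any type)", s$allergic, pct = TRUE, indent = 0),
    fmt("Immediate-type (anaphylaxis)", s$anaphylaxis, pct = TRUE),
    fmt("Mild", s$anaphylaxis$severity$mild, indent = 2),
    fmt("Moderate", s$anaphylaxis$severity$moderate, indent = 2),
    fmt("Severe", s$anaphylaxis$severity$severe, indent = 2),
    fmt("Delayed-type", s$delayed, pct = TRUE),
    fmt("Measles-like (maculopapular) exanthema",
        s$delayed$subtype$maculopapular_exanthema, indent = 2),
    fmt("SDRIFE", s$delayed$subtype$SDRIFE, indent = 2),
    fmt("FDE", s$delayed$subtype$FDE, indent = 2),
    fmt("DRESS", s$delayed$subtype$DRESS, indent = 2)
  )
  lines
}

stratum_counts <- function(leaf) {
  c(de_labelled = as.integer(leaf$de_labelled),
    referred = as.integer(leaf$referred))
}

#' Recompute and verify the full published outcome structure
#'
#' Self-contained reproduction harness: generates the deterministic
#' reference cohort, classifies every record with the five-question
#' algorithm, scores PEN-FAST, builds the stratified accuracy report, and
#' verifies every recomputed quantity against the published outcome
#' structure — the 2x2 table and its four headline metrics, all
#' per-question routing counts, every per-stratum referral split, and the
#' Bayes-consistency of the published PEN-FAST predictive values with its
#' published sensitivity, specificity and prevalence (58/622).
#'
#' @param quiet suppress the rendered report on standard output.
#' @return object of class `reproduction` (invisibly when `quiet = FALSE`):
#'   list with `ok` (logical), `mismatches` (character vector of named
#'   diffs, empty when everything agrees), `report` (the stratified
#'   accuracy report), `two_by_two`, `routing` (route-count tibble),
#'   `headline` (named one-decimal percent strings), `penfast_adjusted`
#'   (named numeric), and `table` (rendered outcome-table lines).
#' @examples
#' rep <- reproduce_paper(quiet = TRUE)
#' rep$ok
#' rep$headline
#' @export
reproduce_paper <- function(quiet = FALSE) {
  exp <- expected_results()
  cohort <- generate_fixture()
  decisions <- apply_algorithm(cohort$histories)
  penfast <- pen_fast(cohort$histories)
  report <- stratified_report(decisions, cohort$truths)
  t22 <- report$counts
  routing <- route_counts(decisions, cohort$truths)
  headline <- vapply(c("sensitivity", "specificity", "ppv", "npv"),
                     function(m) percent1(report_estimate(report, m)),
                     character(1))
  pf_adj <- prevalence_adjusted(exp$penfast_inputs[["sensitivity"]],
                                exp$penfast_inputs[["specificity"]],
                                exp$penfast_inputs[["prevalence"]])

  mismatches <- character(0)
  claim <- function(name, got, want) {
    if (!isTRUE(all(got == want))) {
      mismatches <<- c(mismatches,
                       sprintf("%s: got [%s], expected [%s]", name,
                               paste(got, collapse = ", "),
                               paste(want, collapse = ", ")))
    }
  }
  claim("2x2 table", c(tp = t22$tp, fp = t22$fp, fn = t22$fn, tn = t22$tn),
        exp$two_by_two)
  claim("headline metrics", headline, exp$headline)
  rc <- function(q, rec, alg) {
    routing$n[routing$deciding_question == q &
              routing$recommendation == rec & routing$allergic == alg]
  }
  claim("non-allergic de-labelled Q1-Q3",
        vapply(c("Q1", "Q2", "Q3"), rc, integer(1),
               rec = "de_label", alg = FALSE),
        exp$routing_non_allergic)
  claim("allergic de-labelled Q1/Q2/Q3/Q5",
        vapply(c("Q1", "Q2", "Q3", "Q5"), rc, integer(1),
               rec = "de_label", alg = TRUE),
        exp$routing_allergic_delabel)
  claim("Q4 referrals",
        c(rc("Q4", "alternative_antibiotic", FALSE),
          rc("Q4", "alternative_antibiotic", TRUE)),
        exp$routing_q4)
  claim("Q5 referrals",
        c(rc("Q5", "alternative_antibiotic", FALSE),
          rc("Q5", "alternative_antibiotic", TRUE)),
        exp$routing_q5_alternative)
  s <- report$strata
  leaves <- list(anaphylaxis = s$anaphylaxis,
                 mild = s$anaphylaxis$severity$mild,
                 moderate = s$anaphylaxis$severity$moderate,
                 severe = s$anaphylaxis$severity$severe,
                 moderate_severe = s$anaphylaxis$moderate_severe,
                 delayed = s$delayed,
                 maculopapular_exanthema = s$delayed$subtype$maculopapular_exanthema,
                 SDRIFE = s$delayed$subtype$SDRIFE,
                 FDE = s$delayed$subtype$FDE,
                 DRESS = s$delayed$subtype$DRESS)
  for (nm in names(leaves)) {
    claim(paste("stratum", nm), stratum_counts(leaves[[nm]]),
          exp$strata[[nm]])
  }
  claim("PEN-FAST prevalence-adjusted PPV/NPV",
        percent1(pf_adj), exp$penfast_adjusted)

  out <- structure(list(
    ok = length(mismatches) == 0,
    mismatches = mismatches,
    report = report,
    two_by_two = t22,
    routing = routing,
    headline = headline,
    penfast = penfast,
    penfast_adjusted = pf_adj,
    table = render_table2(report)
  ), class = "reproduction")
  if (!quiet) print(out)
  invisible(out)
}

#' @export
print.reproduction <- function(x, ...) {
  cat(x$table, sep = "\n")
  cat(sprintf("\nsensitivity %s%%, specificity %s%%, PPV %s%%, NPV %s%%\n",
              x$headline[["sensitivity"]], x$headline[["specificity"]],
              x$headline[["ppv"]], x$headline[["npv"]]))
  cat(sprintf("PEN-FAST at prevalence 58/622: PPV %s%%, NPV %s%%\n",
              percent1(x$penfast_adjusted[["ppv"]]),
              percent1(x$penfast_adjusted[["npv"]])))
  if (x$ok) {
    cat("all reproduced quantities match the published outcome structure\n")
  } else {
    cat("MISMATCHES:\n")
    cat(paste0("  ", x$mismatches), sep = "\n")
  }
  invisible(x)
}
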