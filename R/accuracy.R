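#' Build a 2x2 classification-vs-truth table
#'
#' Cross-tabulates a rule's prediction against the adjudicated diagnosis.
#' "Positive" means the rule flags the case as potentially allergic: an
#' `alternative_antibiotic` recommendation from the de-labelling algorithm,
#' or `low_risk = FALSE` from PEN-FAST. So `tp` counts allergic cases
#' referred to an alternative antibiotic and `tn` non-allergic cases
#' de-labelled.
#'
#' @param predictions either a decisions tibble from [apply_algorithm()]
#'   (column `recommendation`), a PEN-FAST result tibble from [pen_fast()]
#'   (column `low_risk`), or a tibble with `case_id` and a logical
#'   `positive` column.
#' @param truths ground-truth tibble; `case_id`s must match one-to-one.
#' @return object of class `two_by_two`: list with integer counts `tp`,
#'   `fp`, `fn`, `tn` and total `n`.
#' @export
contingency <- function(predictions, truths) {
  positive <- if ("recommendation" %in% names(predictions)) {
    predictions$recommendation == "alternative_antibiotic"
  } else if ("low_risk" %in% names(predictions)) {
    !predictions$low_risk
  } else if ("positive" %in% names(predictions)) {
    as.logical(predictions$positive)
  } else {
    abort_delabel(
      "predictions must carry a recommendation, low_risk or positive column",
      "delabelr_usage_error"
    )
  }
  match_cases(predictions$case_id, truths$case_id)
  allergic <- truths$allergic[match(predictions$case_id, truths$case_id)]
  two_by_two(
    tp = sum(positive & allergic),
    fp = sum(positive & !allergic),
    fn = sum(!positive & allergic),
    tn = sum(!positive & !allergic)
  )
}

#' Construct a 2x2 table from counts
#'
#' @param tp,fp,fn,tn non-negative integer counts; `tp` = allergic and
#'   flagged positive (alternative antibiotic), `tn` = non-allergic and
#'   de-labelled.
#' @return object of class `two_by_two`.
#' @export
two_by_two <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    abort_delabel("tp, fp, fn, tn must be non-negative integers",
                  "delabelr_validation_error")
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 n = as.integer(tp + fp + fn + tn)),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("allergic", "non-allergic"),
                              prediction = c("alternative", "de-label")))
  cat("2x2 classification table (n =", x$n, ")\n")
  print(m)
  invisible(x)
}

# Wilson score interval for a binomial proportion; prop.test without
# continuity correction computes exactly this interval
proportion_ci <- function(x, n, ci_level, method = c("wilson", "wald")) {
  method <- match.arg(method)
  if (n == 0) return(c(NA_real_, NA_real_))
  if (method == "wilson") {
    # only the score interval is used; prop.test's chi-squared warning
    # concerns its test statistic, not the interval
    as.numeric(suppressWarnings(
      stats::prop.test(x, n, conf.level = ci_level, correct = FALSE)
    )$conf.int)
  } else {
    p <- x / n
    se <- sqrt(p * (1 - p) / n)
    z <- stats::qnorm(1 - (1 - ci_level) / 2)
    c(max(0, p - z * se), min(1, p + z * se))
  }
}

#' Diagnostic-accuracy metrics with confidence intervals
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' value, and prevalence from a 2x2 table, each with a two-sided binomial
#' confidence interval (Wilson score by default, chosen for its behavior in
#' small strata). A metric whose denominator is zero is reported as `NA`
#' (undefined) rather than an error.
#'
#' @param t a `two_by_two` object.
#' @param ci_level confidence level in (0, 1); default 0.95.
#' @param ci_method `"wilson"` (score interval) or `"wald"`.
#' @return object of class `accuracy_report`: list with `estimates` (tibble
#'   of metric, numerator, denominator, estimate, lower, upper), the source
#'   `counts`, `n`, `ci_level`, and an empty `strata` list (filled by
#'   [stratified_report()]).
#' @examples
#' metrics(two_by_two(tp = 184, fp = 265, fn = 21, tn = 330))
#' @export
metrics <- function(t, ci_level = 0.95, ci_method = c("wilson", "wald")) {
  stopifnot(inherits(t, "two_by_two"))
  ci_method <- match.arg(ci_method)
  if (!(is.numeric(ci_level) && length(ci_level) == 1 &&
        ci_level > 0 && ci_level < 1)) {
    abort_delabel("ci_level must be a single number in (0, 1)",
                  "delabelr_usage_error")
  }
  rows <- list(
    sensitivity = c(t$tp, t$tp + t$fn),
    specificity = c(t$tn, t$tn + t$fp),
    ppv         = c(t$tp, t$tp + t$fp),
    npv         = c(t$tn, t$tn + t$fn),
    prevalence  = c(t$tp + t$fn, t$n)
  )
  est <- lapply(names(rows), function(m) {
    num <- rows[[m]][1]; den <- rows[[m]][2]
    if (den == 0) {
      tibble::tibble(metric = m, numerator = num, denominator = den,
                     estimate = NA_real_, lower = NA_real_, upper = NA_real_)
    } else {
      ci <- proportion_ci(num, den, ci_level, ci_method)
      tibble::tibble(metric = m, numerator = num, denominator = den,
                     estimate = num / den, lower = ci[1], upper = ci[2])
    }
  })
  structure(list(estimates = do.call(rbind, est), counts = t, n = t$n,
                 ci_level = ci_level, ci_method = ci_method,
                 strata = list()),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("Diagnostic accuracy (n = %d, %.0f%% %s CI)\n",
              x$n, 100 * x$ci_level, x$ci_method))
  e <- x$estimates
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %-11s %s%% (%d/%d, CI %s-%s)\n", e$metric[i],
                percent1(e$estimate[i]), e$numerator[i], e$denominator[i],
                percent1(e$lower[i]), percent1(e$upper[i])))
  }
  if (length(x$strata)) {
    cat("  strata:", paste(names(x$strata), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract one metric estimate from an accuracy report
#'
#' @param report an `accuracy_report`.
#' @param metric one of `"sensitivity"`, `"specificity"`, `"ppv"`, `"npv"`,
#'   `"prevalence"`.
#' @return the point estimate as a proportion (possibly `NA`).
#' @export
report_estimate <- function(report, metric) {
  e <- report$estimates
  e$estimate[match(metric, e$metric)]
}

#' Prevalence-adjusted predictive values
#'
#' Recomputes PPV and NPV from sensitivity, specificity and an assumed
#' prevalence via Bayes' theorem, allowing predictive values published for
#' one population to be projected onto another:
#' \deqn{PPV = \frac{se \cdot p}{se \cdot p + (1 - sp)(1 - p)}, \quad
#'       NPV = \frac{sp (1 - p)}{sp (1 - p) + (1 - se) p}}
#'
#' @param sensitivity,specificity,prevalence proportions in \[0, 1\].
#' @return named numeric vector `c(ppv = , npv = )`; a degenerate
#'   denominator yields `NA` for the affected value.
#' @examples
#' prevalence_adjusted(0.707, 0.785, 58 / 622)
#' @export
prevalence_adjusted <- function(sensitivity, specificity, prevalence) {
  args <- c(sensitivity = sensitivity, specificity = specificity,
            prevalence = prevalence)
  if (any(!is.finite(args)) || any(args < 0) || any(args > 1)) {
    abort_delabel("sensitivity, specificity and prevalence must lie in [0, 1]",
                  "delabelr_domain_error")
  }
  p <- prevalence; se <- sensitivity; sp <- specificity
  ppv_den <- se * p + (1 - sp) * (1 - p)
  npv_den <- sp * (1 - p) + (1 - se) * p
  c(ppv = if (ppv_den > 0) se * p / ppv_den else NA_real_,
    npv = if (npv_den > 0) sp * (1 - p) / npv_den else NA_real_)
}

#' Accuracy report stratified by ground-truth diagnosis
#'
#' Builds the overall accuracy report plus nested per-stratum referral
#' tables mirroring the diagnostic hierarchy: immediate-type anaphylaxis
#' (split mild / moderate / severe, plus the pooled moderate-severe
#' stratum) and delayed-type hypersensitivity (split by subtype). Each
#' allergic stratum reports how many cases were de-labelled versus referred
#' to an alternative antibiotic — referral being the correct call for a
#' proven allergy — with a Wilson interval on the referred proportion.
#' Empty strata are omitted rather than reported as 0/0.
#'
#' @param decisions decisions tibble from [apply_algorithm()] (or any
#'   predictions accepted by [contingency()]).
#' @param truths ground-truth tibble matching one-to-one.
#' @param ci_level,ci_method as in [metrics()].
#' @return `accuracy_report` whose `strata` field is a nested list:
#'   `non_allergic`, `allergic`, `anaphylaxis` (with `$severity` sub-list
#'   and `$moderate_severe`), `delayed` (with `$subtype` sub-list). Each
#'   leaf holds `de_labelled`, `referred`, `total`, `referred_prop`,
#'   `lower`, `upper`.
#' @export
stratified_report <- function(decisions, truths, ci_level = 0.95,
                              ci_method = c("wilson", "wald")) {
  ci_method <- match.arg(ci_method)
  overall <- metrics(contingency(decisions, truths), ci_level, ci_method)
  positive <- if ("recommendation" %in% names(decisions)) {
    decisions$recommendation == "alternative_antibiotic"
  } else if ("low_risk" %in% names(decisions)) {
    !decisions$low_risk
  } else {
    as.logical(decisions$positive)
  }
  tr <- truths[match(decisions$case_id, truths$case_id), ]

  leaf <- function(keep) {
    total <- sum(keep)
    if (total == 0) return(NULL)
    referred <- sum(positive[keep])
    ci <- proportion_ci(referred, total, ci_level, ci_method)
    list(de_labelled = total - referred, referred = referred, total = total,
         referred_prop = referred / total, lower = ci[1], upper = ci[2])
  }
  imm <- !is.na(tr$mechanism) & tr$mechanism == "immediate_anaphylaxis"
  del <- !is.na(tr$mechanism) & tr$mechanism == "delayed"

  severity <- Filter(Negate(is.null), stats::setNames(
    lapply(ANAPHYLAXIS_SEVERITY, function(s) {
      leaf(imm & !is.na(tr$anaphylaxis_severity) & tr$anaphylaxis_severity == s)
    }), ANAPHYLAXIS_SEVERITY))
  subtype <- Filter(Negate(is.null), stats::setNames(
    lapply(DELAYED_SUBTYPE, function(s) {
      leaf(del & !is.na(tr$delayed_subtype) & tr$delayed_subtype == s)
    }), DELAYED_SUBTYPE))

  strata <- list(
    non_allergic = leaf(!tr$allergic),
    allergic = leaf(tr$allergic),
    anaphylaxis = c(leaf(imm),
                    list(severity = severity,
                         moderate_severe = leaf(
                           imm & !is.na(tr$anaphylaxis_severity) &
                             tr$anaphylaxis_severity %in% c("moderate", "severe")))),
    delayed = c(leaf(del), list(subtype = subtype))
  )
  overall$strata <- strata
  overall
}
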