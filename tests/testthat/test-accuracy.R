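test_that("contingency counts match direct enumeration on a toy cohort", {
  # 6 records with known predictions and labels
  d <- tibble::tibble(
    case_id = sprintf("t%d", 1:6),
    recommendation = c("alternative_antibiotic", "alternative_antibiotic",
                       "de_label", "de_label",
                       "alternative_antibiotic", "de_label")
  )
  g <- ground_truth(
    case_id = sprintf("t%d", 1:6),
    allergic = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    mechanism = c("delayed", NA, "immediate_anaphylaxis", NA, "delayed", NA),
    anaphylaxis_severity = c(NA, NA, "mild", NA, NA, NA),
    delayed_subtype = c("FDE", NA, NA, NA, "maculopapular_exanthema", NA)
  )
  t22 <- contingency(d, g)
  expect_equal(c(t22$tp, t22$fp, t22$fn, t22$tn), c(2L, 1L, 1L, 2L))
  expect_equal(t22$n, 6L)

  # all-correct cohort of 4: no off-diagonal counts
  d2 <- tibble::tibble(
    case_id = sprintf("c%d", 1:4),
    recommendation = c("alternative_antibiotic", "alternative_antibiotic",
                       "de_label", "de_label")
  )
  g2 <- ground_truth(sprintf("c%d", 1:4), c(TRUE, TRUE, FALSE, FALSE),
                     mechanism = c("delayed", "delayed", NA, NA),
                     delayed_subtype = c("FDE", "DRESS", NA, NA))
  t22 <- contingency(d2, g2)
  expect_equal(t22$fp, 0L)
  expect_equal(t22$fn, 0L)

  # PEN-FAST results plug in with positive = not low risk
  pf <- tibble::tibble(case_id = sprintf("c%d", 1:4),
                       low_risk = c(FALSE, FALSE, TRUE, TRUE))
  t22 <- contingency(pf, g2)
  expect_equal(c(t22$tp, t22$tn), c(2L, 2L))

  expect_error(contingency(d2[1:3, ], g2), "one-to-one")
})

test_that("metric point estimates equal their defining count ratios", {
  t22 <- two_by_two(tp = 184, fp = 265, fn = 21, tn = 330)
  rep <- metrics(t22)
  expect_equal(report_estimate(rep, "sensitivity"), 184 / 205)
  expect_equal(report_estimate(rep, "specificity"), 330 / 595)
  expect_equal(report_estimate(rep, "ppv"), 184 / 449)
  expect_equal(report_estimate(rep, "npv"), 330 / 351)
  expect_equal(report_estimate(rep, "prevalence"), 205 / 800)

  # degenerate table: all metrics 100%
  rep <- metrics(two_by_two(1, 0, 0, 1))
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    expect_equal(report_estimate(rep, m), 1)
  }

  # zero denominators are undefined, not errors
  rep <- metrics(two_by_two(0, 0, 0, 5))
  expect_true(is.na(report_estimate(rep, "sensitivity")))
  expect_true(is.na(report_estimate(rep, "ppv")))
  expect_equal(report_estimate(rep, "specificity"), 1)
})

test_that("percent formatting rounds half-up to one decimal", {
  t22 <- two_by_two(tp = 184, fp = 265, fn = 21, tn = 330)
  rep <- metrics(t22)
  expect_identical(percent1(report_estimate(rep, "sensitivity")), "89.8")
  expect_identical(percent1(report_estimate(rep, "specificity")), "55.5")
  expect_identical(percent1(report_estimate(rep, "ppv")), "41.0")
  expect_identical(percent1(report_estimate(rep, "npv")), "94.0")
  # exact halves round up, unlike round()
  expect_identical(percent1(0.04450), "4.5")
  expect_equal(round_half_up(c(0.25, 0.35, -0.25), 1), c(0.3, 0.4, -0.3))
})

test_that("Wilson intervals match the closed-form score formula", {
  wilson_oracle <- function(x, n, level) {
    z <- qnorm(1 - (1 - level) / 2)
    p <- x / n
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    c(centre - half, centre + half)
  }
  cases <- list(c(184, 205), c(330, 595), c(0, 17), c(17, 17), c(1, 27))
  for (cs in cases) {
    got <- delabelr:::proportion_ci(cs[1], cs[2], 0.95, "wilson")
    expect_equal(got, wilson_oracle(cs[1], cs[2], 0.95), tolerance = 1e-10,
                 info = paste(cs, collapse = "/"))
  }
  # intervals contain their point estimates
  ci <- delabelr:::proportion_ci(184, 205, 0.95, "wilson")
  expect_true(ci[1] <= 184 / 205 && 184 / 205 <= ci[2])
})

test_that("sensitivity CI coverage is near nominal on repeated binomial draws", {
  set.seed(501)
  n_sim <- 800
  n <- 205
  p <- 184 / 205
  x <- rbinom(n_sim, n, p)
  covered <- vapply(x, function(xi) {
    ci <- delabelr:::proportion_ci(xi, n, 0.95, "wilson")
    ci[1] <= p && p <= ci[2]
  }, logical(1))
  mc_se <- sqrt(0.95 * 0.05 / n_sim)
  expect_lt(abs(mean(covered) - 0.95), 4 * mc_se)
})

test_that("prevalence adjustment obeys Bayes' theorem and its identities", {
  # published PEN-FAST operating point
  adj <- prevalence_adjusted(0.707, 0.785, 58 / 622)
  expect_identical(percent1(adj[["ppv"]]), "25.3")
  expect_identical(percent1(adj[["npv"]]), "96.3")

  # perfect test is prevalence-invariant
  for (p in c(0.01, 0.3, 0.99)) {
    expect_equal(unname(prevalence_adjusted(1, 1, p)), c(1, 1))
  }

  # identity with count-based predictive values at the cohort's own
  # prevalence, on random cohorts
  for (seed in c(61, 62, 63)) {
    h <- random_histories(120, seed)
    g <- random_truths(h$case_id, seed + 5)
    rep <- metrics(contingency(apply_algorithm(h), g))
    adj <- prevalence_adjusted(report_estimate(rep, "sensitivity"),
                               report_estimate(rep, "specificity"),
                               report_estimate(rep, "prevalence"))
    expect_equal(adj[["ppv"]], report_estimate(rep, "ppv"), tolerance = 1e-12)
    expect_equal(adj[["npv"]], report_estimate(rep, "npv"), tolerance = 1e-12)
  }

  # domain errors and degenerate denominators
  expect_error(prevalence_adjusted(1.2, 0.5, 0.1), "0, 1")
  expect_error(prevalence_adjusted(0.9, -0.1, 0.1), "0, 1")
  degenerate <- prevalence_adjusted(0, 1, 0.5)
  expect_true(is.na(degenerate[["ppv"]]))
})

test_that("strata partition the marginal table on arbitrary cohorts", {
  for (seed in c(71, 72)) {
    h <- random_histories(250, seed)
    g <- random_truths(h$case_id, seed + 9)
    d <- apply_algorithm(h)
    rep <- stratified_report(d, g)
    s <- rep$strata
    t22 <- rep$counts
    # allergic/non-allergic strata reproduce the 2x2 margins
    expect_equal(s$allergic$referred, t22$tp)
    expect_equal(s$allergic$de_labelled, t22$fn)
    expect_equal(s$non_allergic$de_labelled, t22$tn)
    expect_equal(s$non_allergic$referred, t22$fp)
    # severity strata sum to the anaphylaxis stratum
    if (!is.null(s$anaphylaxis$total)) {
      sev <- s$anaphylaxis$severity
      expect_equal(sum(vapply(sev, `[[`, numeric(1), "total")),
                   s$anaphylaxis$total)
    }
    # subtype strata sum to the delayed stratum
    if (!is.null(s$delayed$total)) {
      sub <- s$delayed$subtype
      expect_equal(sum(vapply(sub, `[[`, numeric(1), "total")),
                   s$delayed$total)
    }
  }
})

test_that("empty strata are omitted rather than zero-divided", {
  h <- random_histories(10, 81)
  g <- ground_truth(h$case_id, allergic = rep(FALSE, 10))
  rep <- stratified_report(apply_algorithm(h), g)
  expect_null(rep$strata$allergic)
  expect_null(rep$strata$anaphylaxis$total)
  expect_equal(rep$strata$non_allergic$total, 10)
})
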