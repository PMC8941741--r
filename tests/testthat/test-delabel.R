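test_that("question predicates follow the documented clinical semantics", {
  # Q1: incompatible complaints (isolated headache) or clearly late onset
  h <- blank_history("q1a", symptoms_incompatible_with_allergy = "yes")
  expect_equal(evaluate_question("Q1", h), "yes")
  h <- blank_history("q1b", onset_latency = "days_urticaria_gt2")
  expect_equal(evaluate_question("Q1", h), "yes")
  h <- blank_history("q1c", onset_latency = "weeks_exanthema_gt1")
  expect_equal(evaluate_question("Q1", h), "yes")
  h <- blank_history("q1d", onset_latency = "unknown")
  expect_equal(evaluate_question("Q1", h), "uncertain")

  # Q2: childhood rash without systemic symptoms; adult age overrides
  h <- blank_history("q2a", rash_in_childhood_no_systemic = "yes",
                     age_at_reaction_years = 10)
  expect_equal(evaluate_question("Q2", h), "yes")
  h <- blank_history("q2b", rash_in_childhood_no_systemic = "yes",
                     age_at_reaction_years = 30)
  expect_equal(evaluate_question("Q2", h), "no")
  h <- blank_history("q2c", rash_in_childhood_no_systemic = "yes",
                     age_at_reaction_years = NA)
  expect_equal(evaluate_question("Q2", h), "yes")
  # configurable adulthood bound
  h <- blank_history("q2d", rash_in_childhood_no_systemic = "yes",
                     age_at_reaction_years = 20)
  expect_equal(evaluate_question("Q2", h, adult_threshold = 21), "yes")

  # Q3 / Q4 mirror their tri-state driver fields
  h <- blank_history("q3a")
  expect_equal(evaluate_question("Q3", h), "no")
  h <- blank_history("q3b", prolonged_urticaria_no_systemic = "uncertain")
  expect_equal(evaluate_question("Q3", h), "uncertain")
  h <- blank_history("q4a", measles_like_exanthema_adult = "yes")
  expect_equal(evaluate_question("Q4", h), "yes")

  # Q5: any severe indicator, including an incident during anesthesia
  h <- blank_history("q5a", severe_indicators = "incident_during_anesthesia")
  expect_equal(evaluate_question("Q5", h), "yes")
  h <- blank_history("q5b")
  expect_equal(evaluate_question("Q5", h), "no")

  expect_error(evaluate_question("Q6", h), "unknown question")
})

test_that("the algorithm routes and recommends per the decision tree", {
  # FDE-like: blisters reported, Q1-Q4 negative -> high risk at Q5
  h <- blank_history("fde", severe_indicators = "cutaneous_blisters")
  d <- apply_algorithm(h)
  expect_equal(d$recommendation, "alternative_antibiotic")
  expect_equal(d$deciding_question, "Q5")

  # adult maculopapular exanthema -> avoid penicillin via Q4
  h <- blank_history("mpe", measles_like_exanthema_adult = "yes")
  d <- apply_algorithm(h)
  expect_equal(d$recommendation, "alternative_antibiotic")
  expect_equal(d$deciding_question, "Q4")

  # everything negative, no severe evidence -> de-label at Q5
  d <- apply_algorithm(blank_history("neg"))
  expect_equal(d$recommendation, "de_label")
  expect_equal(d$deciding_question, "Q5")

  # uncertain at Q5's drivers resolves to de-label (residual-risk locus)
  h <- blank_history("unc", symptoms_incompatible_with_allergy = "uncertain",
                     onset_latency = "unknown")
  d <- apply_algorithm(h)
  expect_equal(d$recommendation, "de_label")
  expect_equal(d$deciding_question, "Q5")

  # first yes wins: Q1 decides even when Q4 would also be yes
  h <- blank_history("ord", symptoms_incompatible_with_allergy = "yes",
                     measles_like_exanthema_adult = "yes")
  d <- apply_algorithm(h)
  expect_equal(d$deciding_question, "Q1")
  expect_equal(d$recommendation, "de_label")
})

test_that("answer traces visit Q1-Q4 in order with no yes before the deciding question", {
  h <- random_histories(400, 7)
  d <- apply_algorithm(h)
  qcols <- as.matrix(d[, c("Q1", "Q2", "Q3", "Q4", "Q5")])
  for (i in seq_len(nrow(d))) {
    dq <- match(d$deciding_question[i], c("Q1", "Q2", "Q3", "Q4", "Q5"))
    before <- qcols[i, seq_len(dq - 1)]
    after <- qcols[i, setdiff(seq_len(5), seq_len(dq))]
    expect_true(all(before %in% c("no", "uncertain")))
    expect_true(all(is.na(after)))
    expect_false(is.na(qcols[i, dq]))
  }
})

test_that("recommendation is consistent with the deciding question on random inputs", {
  h <- random_histories(600, 8)
  d <- apply_algorithm(h)
  expect_true(all(d$recommendation[d$deciding_question %in% c("Q1", "Q2", "Q3")] == "de_label"))
  expect_true(all(d$recommendation[d$deciding_question == "Q4"] == "alternative_antibiotic"))
  q5 <- d$deciding_question == "Q5"
  expect_true(all(d$recommendation[q5 & d$Q5 == "yes"] == "alternative_antibiotic"))
  expect_true(all(d$recommendation[q5 & d$Q5 != "yes"] == "de_label"))
  # determinism: identical histories yield identical decisions
  expect_identical(d, apply_algorithm(h))
})

test_that("adding a severe indicator never converts a referral into de-labelling", {
  h <- random_histories(200, 9)
  before <- apply_algorithm(h)
  set.seed(10)
  extra <- sample(SEVERE_INDICATORS, nrow(h), TRUE)
  h2 <- h
  h2$severe_indicators <- vapply(seq_len(nrow(h)), function(i) {
    cur <- h$severe_indicators[i]
    if (cur == "") return(extra[i])
    if (extra[i] %in% strsplit(cur, ";", fixed = TRUE)[[1]]) return(cur)
    paste(cur, extra[i], sep = ";")
  }, character(1))
  after <- apply_algorithm(h2)
  flipped <- before$recommendation == "alternative_antibiotic" &
    after$recommendation == "de_label"
  expect_false(any(flipped))
})

test_that("route counts cover the full grid and sum to the cohort", {
  h <- random_histories(150, 12)
  g <- random_truths(h$case_id, 13)
  d <- apply_algorithm(h)
  rc <- route_counts(d, g)
  expect_equal(sum(rc$n), 150)
  expect_equal(nrow(rc), 5 * 2 * 2)
  # marginalizing over the deciding question recovers the 2x2 table
  t22 <- contingency(d, g)
  expect_equal(sum(rc$n[rc$recommendation == "alternative_antibiotic" & rc$allergic]), t22$tp)
  expect_equal(sum(rc$n[rc$recommendation == "de_label" & !rc$allergic]), t22$tn)

  # empty cohort: all-zero table
  rc0 <- route_counts(apply_algorithm(random_histories(0, 1)),
                      random_truths(character(0), 1))
  expect_true(all(rc0$n == 0))

  # unmatched ids rejected
  g_bad <- g
  g_bad$case_id[1] <- "nope"
  expect_error(route_counts(d, g_bad), "one-to-one")
})
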