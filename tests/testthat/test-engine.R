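def <- default_algorithm()

test_that("a fresh session starts at the first danger-sign question", {
  s <- new_session(def, age_months = 24)
  q <- next_question(def, s)
  expect_identical(q$id, "danger_drink")
  expect_identical(q$block, "danger_signs")
  expect_identical(s$status, "in_progress")
})

test_that("a confirmed symptom opens its severity block, a denied one skips it", {
  s <- new_session(def, 24)
  s <- record_answer(def, s, "danger_drink", "no")
  s <- record_answer(def, s, "danger_convulsions", "no")
  s_yes <- record_answer(def, s, "fever", "yes")
  expect_identical(next_question(def, s_yes)$id, "fever_stiff_neck")
  s_no <- record_answer(def, s, "fever", "no")
  expect_identical(next_question(def, s_no)$id, "cough")
})

test_that("answers trigger the dashed-arrow assessment emissions", {
  s <- new_session(def, 24)
  s <- record_answer(def, s, "danger_drink", "no")
  s <- record_answer(def, s, "danger_convulsions", "yes")
  expect_true("neurological_emergency" %in% s$emitted)

  # blood in stool after confirmed diarrhoea emits dysentery
  rec <- run_session(def, all_no_except(def, c("diarrhoea", "gi_blood_stool")), 24)
  expect_true("dysentery" %in% rec$assessments)
  expect_identical(rec$recommendation, "B")
})

test_that("no-response abandons the session without new emissions", {
  s <- new_session(def, 24)
  s <- record_answer(def, s, "danger_drink", "no_response")
  expect_identical(s$status, "abandoned")
  expect_identical(s$emitted, character())
  expect_error(record_answer(def, s, "danger_convulsions", "no"), "path error")
})

test_that("out-of-order answers and unknown codes are rejected", {
  s <- new_session(def, 24)
  expect_error(record_answer(def, s, "fever", "yes"), "path error")
  expect_error(record_answer(def, s, "danger_drink", "maybe"), "unknown answer")
})

test_that("keypad codes map onto the dichotomous alphabet", {
  expect_identical(normalize_answer(c("1", "2", "YES", "No", "")),
                   c("yes", "no", "yes", "no", "no_response"))
  expect_error(normalize_answer("7"), "unknown answer")
})

test_that("triage picks the most life-threatening condition", {
  expect_identical(triage("febrile_disease", def), "B")
  expect_identical(triage(c("mild_rti", "severe_rti", "febrile_disease"), def), "A")
  expect_identical(triage(character(), def), TRIAGE_NONE)
  expect_error(triage("not_a_condition", def), "catalogue error")
})

test_that("adding an assessment never lowers the triage severity", {
  ids <- names(def$assessments)
  rank_of <- function(set) {
    code <- triage(set, def)
    if (identical(code, TRIAGE_NONE)) 0L else severity_rank(code)
  }
  set.seed(101)
  for (i in 1:50) {
    base <- sample(ids, sample(0:4, 1))
    extra <- sample(setdiff(ids, base), 1)
    expect_gte(rank_of(c(base, extra)), rank_of(base))
  }
})

test_that("complete sessions yield the expected recommendations", {
  all_no <- run_session(def, rep("no", 15), 24)
  expect_identical(all_no$status, "complete")
  expect_identical(all_no$assessments, character())
  expect_identical(all_no$recommendation, TRIAGE_NONE)

  danger <- run_session(def, all_no_except(def, "danger_drink"), 24)
  expect_identical(danger$recommendation, "A")
  expect_true("inability_to_drink" %in% danger$assessments)

  # fever yes, every follow-up no: febrile disease alone, level B
  fever_only <- run_session(def, all_no_except(def, "fever"), 24)
  expect_identical(fever_only$assessments, "febrile_disease")
  expect_identical(fever_only$recommendation, "B")
})

test_that("truncated scripts abandon the call and carry no recommendation", {
  rec <- run_session(def, c("no", "no"), 24)
  expect_identical(rec$status, "abandoned")
  expect_true(is.na(rec$recommendation))
  expect_identical(nrow(rec$answers), 3L)  # the third answer is the hang-up
})

test_that("sessions are deterministic and replay-equivalent", {
  set.seed(7)
  for (i in 1:25) {
    answers <- sample(c("yes", "no"), 15, replace = TRUE)
    a <- run_session(def, answers, 24)
    b <- run_session(def, answers, 24)
    expect_identical(a, b)
    replayed <- replay_session(def, a$answers, 24)
    expect_setequal(replayed$emitted, a$assessments)
    expect_identical(replayed$status, a$status)
  }
})

test_that("every complete session respects the question cap", {
  lens <- vapply(enumerate_paths(def), function(p) length(p$answers), integer(1))
  expect_true(all(lens <= def$question_cap))
  expect_identical(max(lens), 13L)
})

test_that("children outside the eligible age window are rejected at start", {
  expect_error(new_session(def, 0.5), "eligibility")
  expect_error(new_session(def, 180), "eligibility")
  expect_error(run_session(def, rep("no", 15), 200), "eligibility")
  expect_silent(new_session(def, 1))
  expect_silent(new_session(def, 179.5))
})
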