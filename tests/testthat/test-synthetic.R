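test_that("cohort truth frequencies match the configured prevalences", {
  n <- 10000
  cfg <- cohort_config(n = n, seed = 17)
  co <- sample_cohort(cfg)
  for (s in c("fever", "cough", "diarrhoea", "vomiting")) {
    p <- cfg$prevalence[[s]]
    tol <- 3 * sqrt(p * (1 - p) / n)  # 3 Monte-Carlo standard errors
    expect_lt(abs(mean(co[[s]]) - p), tol)
  }
  expect_true(all(co$age_months >= 1 & co$age_months < 180))
  expect_true(all(co$rti_grade[!co$cough] == "none"))
  expect_true(all(is.na(co$dehydration[!(co$diarrhoea | co$vomiting)])))
})

test_that("the same seed reproduces the cohort bitwise", {
  cfg <- cohort_config(n = 300, seed = 5)
  expect_identical(sample_cohort(cfg), sample_cohort(cfg))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(prevalence = c(fever = 1.2, cough = 0.5,
                                            diarrhoea = 0.1, vomiting = 0.2)),
               "\\[0, 1\\]")
  expect_error(cohort_config(dropout_prob = -0.1), "\\[0, 1\\]")
  expect_error(reporting_model(c(q_fever = 1.5), c(q_fever = 0.9)), "\\[0, 1\\]")
})

test_that("the physician-standard label is a deterministic function of truth", {
  cfg <- cohort_config(n = 100, seed = 29)
  co <- sample_cohort(cfg)
  def <- default_algorithm()
  for (i in seq_len(20)) {
    scr <- answers_from_truth(co[i, ], perfect_reporting_model(), def)
    rec <- run_session(def, scr$answers, co$age_months[[i]])
    expect_identical(rec$recommendation, co$physician_triage[[i]])
  }
})

test_that("a perfect reporting model reproduces the truth path", {
  cfg <- cohort_config(n = 50, seed = 43)
  co <- sample_cohort(cfg)
  def <- default_algorithm()
  model <- perfect_reporting_model()
  for (i in seq_len(10)) {
    a <- answers_from_truth(co[i, ], model, def)
    b <- answers_from_truth(co[i, ], model, def)
    expect_identical(a, b)  # no randomness left when sens = spec = 1
  }
})

test_that("zero report sensitivity suppresses every true symptom report", {
  cfg <- cohort_config(n = 200, seed = 47)
  co <- sample_cohort(cfg)
  model <- perfect_reporting_model()
  model$sensitivity[["q_fever"]] <- 0
  set.seed(1)
  def <- default_algorithm()
  for (i in which(co$fever)[1:20]) {
    scr <- answers_from_truth(co[i, ], model, def)
    rec <- run_session(def, scr$answers, co$age_months[[i]])
    fever_ans <- rec$answers$answer[rec$answers$node == "fever"]
    expect_identical(fever_ans, "no")
  }
})

test_that("a model missing a question on the path is rejected", {
  cfg <- cohort_config(n = 5, seed = 3)
  co <- sample_cohort(cfg)
  model <- reporting_model(c(q_fever = 1), c(q_fever = 1))
  expect_error(answers_from_truth(co[1, ], model), "does not cover")
})

test_that("perfect reporting gives perfect detection and zero under-triage", {
  sim <- simulate_study(cohort_config(n = 600, dropout_prob = 0, seed = 13),
                        perfect_reporting_model())
  expect_identical(sim$counts[["abandoned"]], 0L)
  expect_true(all(sim$symptom_stats$kappa == 1))
  expect_identical(sim$triage_stats$undertriage, 0)
  expect_identical(sim$triage_stats$agreement, 1)
})

test_that("a symptom-free cohort yields only not-applicable recommendations", {
  cfg <- cohort_config(
    n = 100,
    prevalence = c(fever = 0, cough = 0, diarrhoea = 0, vomiting = 0),
    danger_prevalence = c(inability_to_drink = 0, convulsions = 0,
                          stiff_neck = 0),
    dropout_prob = 0, seed = 19)
  sim <- simulate_study(cfg, perfect_reporting_model())
  expect_true(all(sim$paired$tool_triage == TRIAGE_NONE))
  expect_identical(sim$counts[["evaluable"]], 0L)
})

test_that("the dropout process abandons roughly the configured fraction", {
  cfg <- cohort_config(n = 2000, seed = 53)
  sim <- simulate_study(cfg)
  p <- cfg$dropout_prob
  tol <- 3 * sqrt(p * (1 - p) / cfg$n)
  expect_lt(abs(sim$counts[["abandoned"]] / cfg$n - p), tol)
  expect_true(all(sim$log$recommendation[sim$log$status == "abandoned"] == ""))
})

test_that("simulation output is bitwise reproducible under a fixed seed", {
  cfg <- cohort_config(n = 400, seed = 61)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$log, b$log)
  expect_identical(a$symptom_stats, b$symptom_stats)
  expect_identical(a$triage_table, b$triage_table)
})

test_that("report sensitivity and specificity are recovered from the study", {
  n <- 10000
  model <- study_reporting_model()
  sim <- simulate_study(cohort_config(n = n, dropout_prob = 0, seed = 67), model)
  ss <- sim$symptom_stats
  for (s in c("fever", "cough", "diarrhoea", "vomiting")) {
    key <- paste0("q_", s)
    row <- ss[ss$symptom == s, ]
    for (stat in c("sensitivity", "specificity")) {
      target <- model[[stat]][[key]]
      denom <- if (stat == "sensitivity") row$tp + row$fn else row$tn + row$fp
      tol <- 3 * sqrt(target * (1 - target) / denom)
      expect_lt(abs(row[[stat]] - target), tol)
    }
  }
})
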