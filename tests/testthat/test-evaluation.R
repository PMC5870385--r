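test_that("tabulate_labels matches a naive pair-counting oracle", {
  set.seed(31)
  cats <- c("A", "B", "C")
  for (i in 1:20) {
    tool <- sample(cats, 100, replace = TRUE)
    phys <- sample(cats, 100, replace = TRUE)
    tab <- tabulate_labels(tool, phys, cats)
    for (r in cats) for (co in cats) {
      expect_identical(tab[r, co], sum(tool == r & phys == co))
    }
    expect_identical(sum(tab), 100L)
  }
})

test_that("tabulate_labels rejects unknown labels and ragged input", {
  expect_error(tabulate_labels("A", c("A", "B"), c("A", "B")), "equal length")
  expect_error(tabulate_labels("A", "D", c("A", "B", "C")), "unknown label")
})

test_that("identical label vectors give a diagonal table with full agreement", {
  x <- rep(c("A", "B", "C"), times = c(5, 3, 2))
  tab <- tabulate_labels(x, x, c("A", "B", "C"))
  expect_identical(sum(tab) , sum(diag(tab)))
  expect_identical(percent_agreement(tab), 1)
  expect_identical(cohens_kappa(tab)$kappa, 1)
})

test_that("the published triage table reproduces its printed statistics", {
  tab <- table4_counts()
  expect_identical(sum(tab), 237L)
  expect_identical(round_half_up(100 * percent_agreement(tab), 1), 39.2)
  ks <- cohens_kappa(tab)
  expect_identical(round_half_up(ks$kappa, 2), 0.11)
  expect_lt(ks$p_value, 0.01)
  expect_identical(ks$landis_koch, "slight")
})

test_that("the shipped fixture equals the published triage counts", {
  expect_identical(unclass(study_triage_table()), table4_counts())
})

test_that("kappa is invariant under simultaneous category permutation", {
  set.seed(37)
  for (i in 1:10) {
    tab <- matrix(rpois(9, 20), 3, 3,
                  dimnames = list(tool = c("A", "B", "C"),
                                  physician = c("A", "B", "C")))
    perm <- sample(3)
    expect_equal(cohens_kappa(tab[perm, perm])$kappa,
                 cohens_kappa(tab)$kappa, tolerance = 1e-12)
  }
})

test_that("kappa equals 1 iff diagonal, never exceeds observed agreement", {
  set.seed(41)
  for (i in 1:20) {
    tab <- matrix(rpois(9, 10), 3, 3,
                  dimnames = list(tool = c("A", "B", "C"),
                                  physician = c("A", "B", "C")))
    ks <- cohens_kappa(tab)
    expect_gte(ks$kappa, -1)
    expect_lte(ks$kappa, ks$po)
    is_diag <- sum(diag(tab)) == sum(tab)
    expect_identical(isTRUE(all.equal(ks$kappa, 1)), is_diag)
  }
})

test_that("rows proportional to column marginals give kappa 0", {
  # independence by construction: po equals pe
  col <- c(2, 5, 3)
  tab <- outer(c(10, 20, 10), col)  # row i = weight_i * column profile
  dimnames(tab) <- list(tool = c("A", "B", "C"), physician = c("A", "B", "C"))
  expect_equal(cohens_kappa(tab)$kappa, 0, tolerance = 1e-12)
})

test_that("degenerate marginals give NA kappa, not a crash", {
  tab <- matrix(c(10L, 0L, 0L, 0L), 2, 2,
                dimnames = list(tool = c("y", "n"), physician = c("y", "n")))
  ks <- cohens_kappa(tab)
  expect_true(is.na(ks$kappa))
  expect_error(cohens_kappa(matrix(0L, 2, 2)), "non-empty")
  expect_error(cohens_kappa(matrix(1L, 2, 3)), "square")
})

test_that("binary_metrics reproduces the fever detection row", {
  m <- binary_metrics(tp = 151, fn = 16, fp = 23, tn = 47)
  expect_identical(round_half_up(100 * m$sensitivity, 1), 90.4)
  expect_identical(round_half_up(100 * m$specificity, 1), 67.1)
  expect_identical(round_half_up(100 * m$ppv, 1), 86.8)
  expect_identical(round_half_up(100 * m$npv, 1), 74.6)
  expect_identical(round_half_up(100 * m$prevalence, 1), 70.5)
  expect_identical(round_half_up(100 * m$agreement, 1), 83.5)
})

test_that("zero denominators propagate NA, never 0", {
  m <- binary_metrics(0, 0, 0, 10)
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$ppv))
  expect_identical(m$specificity, 1)
  expect_identical(m$npv, 1)
  expect_identical(m$prevalence, 0)
  expect_error(binary_metrics(-1, 0, 0, 0), "non-negative")
})

test_that("reconstruct_confusion finds the unique fever and cough tables", {
  rc <- reconstruct_confusion(237, 70.5, 90.4, 67.1, agreement = 83.5)
  expect_identical(c(rc$tp, rc$fn, rc$fp, rc$tn), c(151L, 16L, 23L, 47L))
  expect_true(rc$exact)

  rc <- reconstruct_confusion(237, 54.9, 91.5, 71.0, agreement = 82.3)
  expect_identical(c(rc$tp, rc$fn, rc$fp, rc$tn), c(119L, 11L, 31L, 76L))
  expect_identical(round_half_up(100 * rc$metrics$agreement, 1), 82.3)
})

test_that("reconstruct_confusion handles an all-positive cohort", {
  rc <- reconstruct_confusion(10, 100, 100, NA)
  expect_identical(c(rc$tp, rc$fn, rc$fp, rc$tn), c(10L, 0L, 0L, 0L))
})

test_that("reconstruct_confusion round-trips through binary_metrics", {
  # every implied statistic re-rounds onto (or within one unit of) the input
  cells <- reconstructed_cells()
  printed <- list(
    fever = c(70.5, 90.4, 67.1), cough = c(54.9, 91.5, 71.0),
    diarrhoea = c(18.1, 86.1, 84.0), vomiting = c(24.5, 67.2, 79.3),
    febrile_disease = c(70.5, 83.2, 68.6))
  for (nm in names(cells)) {
    p <- printed[[nm]]
    rc <- reconstruct_confusion(237, p[1], p[2], p[3])
    expect_identical(c(rc$tp, rc$fn, rc$fp, rc$tn), cells[[nm]])
    m <- rc$metrics
    expect_lte(abs(round_half_up(100 * m$prevalence, 1) - p[1]), 0.1)
    expect_lte(abs(round_half_up(100 * m$sensitivity, 1) - p[2]), 0.1)
    expect_lte(abs(round_half_up(100 * m$specificity, 1) - p[3]), 0.1)
  }
})

test_that("irreconcilable summaries raise an inconsistency error", {
  expect_error(reconstruct_confusion(237, 50.0, 99.9, 1.3),
               "inconsistency error")
})

test_that("dichotomization collapses the triage table to hospital vs home", {
  tab <- table4_counts()
  d <- dichotomize_triage(tab)
  expect_identical(unclass(d),
                   matrix(c(216L, 7L, 10L, 4L), 2, 2,
                          dimnames = list(tool = c("hospital", "home"),
                                          physician = c("hospital", "home"))))
  expect_identical(round_half_up(100 * percent_agreement(d), 1), 92.8)
  expect_identical(round_half_up(cohens_kappa(d)$kappa, 2), 0.28)
  expect_identical(cohens_kappa(d)$landis_koch, "fair")

  all_c <- tabulate_labels(rep("C", 9), rep("C", 9), c("A", "B", "C"))
  expect_identical(dichotomize_triage(all_c)["home", "home"], 9L)
})

test_that("under-triage and capture rates match the published counts", {
  tab <- table4_counts()
  expect_identical(round_half_up(100 * undertriage_rate(tab), 1), 3.0)
  expect_identical(capture_rate(tab, "A"), 42 / 48)
  diag_tab <- tabulate_labels(rep(c("A", "B", "C"), 4), rep(c("A", "B", "C"), 4),
                              c("A", "B", "C"))
  expect_identical(undertriage_rate(diag_tab), 0)
})
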