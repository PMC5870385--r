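# Synthetic study cohorts: true child states drawn from configurable
# marginal prevalences, a per-question guardian misreporting model, and an
# end-to-end harness that mirrors the hospital validation design (recruit,
# drop out, call the hotline, compare against the truth-derived standard).

# prompt keys of the default tree, in ask order
PROMPT_KEYS <- c("q_danger_drink", "q_convulsions", "q_fever", "q_stiff_neck",
                 "q_cough", "q_breathing_inability", "q_noisy_breathing",
                 "q_fast_breathing", "q_diarrhoea", "q_blood_stool",
                 "q_vomiting", "q_lethargic", "q_sunken_eyes")

#' Configuration of a synthetic study cohort
#'
#' Defaults emulate the hospital validation cohort: 294 recruited calls of
#' which a fraction 27/294 drop out before completing the questions; symptom
#' prevalences equal to the physician-standard prevalences of the study
#' (fever 70.5\%, cough 54.9\%, diarrhoea 18.1\%, vomiting 24.5\%); severity
#' grades distributed proportionally to the published assessment
#' prevalences, conditional on the parent symptom; and danger signs at the
#' study's (near-zero) physician rates.
#'
#' @param n number of recruited calls.
#' @param prevalence named probabilities for `fever`, `cough`, `diarrhoea`,
#'   `vomiting` (independent Bernoulli draws; the study reports only
#'   marginals).
#' @param danger_prevalence named probabilities for `inability_to_drink`,
#'   `convulsions`, `stiff_neck` (the latter conditional on fever).
#' @param rti_grades unnormalised weights for grades `severe`, `moderate`,
#'   `mild` of respiratory infection, conditional on true cough.
#' @param blood_given_diarrhoea probability of blood in stool given true
#'   diarrhoea.
#' @param dehydration_grades unnormalised weights for `severe`, `some`,
#'   `none` dehydration, conditional on a true gastrointestinal symptom
#'   (diarrhoea or vomiting).
#' @param dropout_prob probability a call is abandoned before completion.
#' @param seed optional integer seed carried with the configuration.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 294,
                          prevalence = c(fever = 0.705, cough = 0.549,
                                         diarrhoea = 0.181, vomiting = 0.245),
                          danger_prevalence = c(inability_to_drink = 0,
                                                convulsions = 1 / 237,
                                                stiff_neck = 0),
                          rti_grades = c(severe = 0.093, moderate = 0.279,
                                         mild = 0.224),
                          blood_given_diarrhoea = 0.030 / 0.181,
                          dehydration_grades = c(severe = 0.025, some = 0.063,
                                                 none = 0.262),
                          dropout_prob = 27 / 294,
                          seed = NULL) {
  stopifnot(n >= 1, n == round(n))
  probs <- c(prevalence, danger_prevalence, blood_given_diarrhoea, dropout_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(rti_grades < 0) || any(dehydration_grades < 0)) {
    stop("grade weights must be non-negative")
  }
  need <- c("fever", "cough", "diarrhoea", "vomiting")
  stopifnot(all(need %in% names(prevalence)),
            all(c("inability_to_drink", "convulsions", "stiff_neck") %in%
                  names(danger_prevalence)),
            all(c("severe", "moderate", "mild") %in% names(rti_grades)),
            all(c("severe", "some", "none") %in% names(dehydration_grades)))
  structure(
    list(n = as.integer(n), prevalence = prevalence,
         danger_prevalence = danger_prevalence,
         rti_grades = rti_grades / sum(rti_grades),
         blood_given_diarrhoea = blood_given_diarrhoea,
         dehydration_grades = dehydration_grades / sum(dehydration_grades),
         dropout_prob = dropout_prob, seed = seed),
    class = "cohort_config"
  )
}

#' Guardian reporting model
#'
#' Per-question report accuracy of the guardian: the probability of
#' answering "yes" when the underlying state is truly present
#' (`sensitivity`) and of answering "no" when it is truly absent
#' (`specificity`), keyed by prompt id.
#'
#' @param sensitivity,specificity named numeric vectors over prompt keys
#'   (see `ivrtriage:::PROMPT_KEYS`); probabilities in \[0, 1\].
#' @return A list of class `reporting_model`.
#' @seealso [perfect_reporting_model()], [study_reporting_model()]
#' @export
reporting_model <- function(sensitivity, specificity) {
  stopifnot(is.numeric(sensitivity), is.numeric(specificity),
            !is.null(names(sensitivity)), !is.null(names(specificity)))
  if (any(c(sensitivity, specificity) < 0 | c(sensitivity, specificity) > 1)) {
    stop("report sensitivities/specificities must lie in [0, 1]")
  }
  structure(list(sensitivity = sensitivity, specificity = specificity),
            class = "reporting_model")
}

#' @rdname reporting_model
#' @return `perfect_reporting_model()` — every question answered exactly
#'   according to the true state.
#' @export
perfect_reporting_model <- function() {
  one <- stats::setNames(rep(1, length(PROMPT_KEYS)), PROMPT_KEYS)
  reporting_model(one, one)
}

#' Study-calibrated guardian reporting model
#'
#' Report accuracies calibrated to the hospital validation study: for the
#' four symptom screens and the follow-up questions with published
#' comparisons, sensitivity and specificity are the exact cell fractions of
#' the reconstructed tool-versus-physician 2x2 tables (e.g. fever 151/167
#' and 47/70). The two items the physicians never identified (inability to
#' drink/breastfeed, stiff neck) have no estimable accuracy; their report
#' specificity defaults to 0.90 — a modest false-alarm rate in line with the
#' other danger-sign question — and their sensitivity to 0.5 (inconsequential
#' at zero true prevalence).
#'
#' @return A `reporting_model`.
#' @export
study_reporting_model <- function() {
  sens <- c(
    q_danger_drink = 0.5, q_convulsions = 0 / 1, q_fever = 151 / 167,
    q_stiff_neck = 0.5, q_cough = 119 / 130,
    q_breathing_inability = 12 / 22, q_noisy_breathing = 0.5,
    q_fast_breathing = 18 / 66, q_diarrhoea = 37 / 43,
    q_blood_stool = 5 / 7, q_vomiting = 39 / 58,
    q_lethargic = 1 / 6, q_sunken_eyes = 10 / 15
  )
  spec <- c(
    q_danger_drink = 0.90, q_convulsions = 183 / 236, q_fever = 47 / 70,
    q_stiff_neck = 0.90, q_cough = 76 / 107,
    q_breathing_inability = 187 / 215, q_noisy_breathing = 1,
    q_fast_breathing = 133 / 171, q_diarrhoea = 163 / 194,
    q_blood_stool = 194 / 230, q_vomiting = 142 / 179,
    q_lethargic = 220 / 231, q_sunken_eyes = 184 / 222
  )
  reporting_model(sens, spec)
}

#' Draw a synthetic cohort of true child states
#'
#' Samples `n` independent children: age (months, roughly exponential with
#' median three years, clamped to the eligible window), the four symptom
#' flags, danger signs, and conditional severity grades. The
#' physician-standard triage label of each child is derived
#' deterministically from the true flags via the same assessment-to-level
#' catalogue the tool uses (discrepancies between tool and standard are
#' injected only through the guardian reporting model).
#'
#' @param config a [cohort_config()].
#' @param def the algorithm used to derive the physician-standard label.
#' @param seed optional seed (defaults to `config$seed`; `NULL` leaves the
#'   RNG state untouched).
#' @return A data frame of class `true_cohort`, one row per child:
#'   `age_months`, logical truth flags, `rti_grade`, `dehydration`
#'   (`NA` when no gastrointestinal symptom), and `physician_triage`.
#' @export
sample_cohort <- function(config, def = default_algorithm(),
                          seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  p <- config$prevalence
  dp <- config$danger_prevalence

  age <- pmin(pmax(round(stats::rexp(n, rate = log(2) / 36)), 1),
              def$age_limits[2] - 1)
  fever <- stats::runif(n) < p[["fever"]]
  cough <- stats::runif(n) < p[["cough"]]
  diarrhoea <- stats::runif(n) < p[["diarrhoea"]]
  vomiting <- stats::runif(n) < p[["vomiting"]]
  danger_drink <- stats::runif(n) < dp[["inability_to_drink"]]
  convulsions <- stats::runif(n) < dp[["convulsions"]]
  stiff_neck <- fever & (stats::runif(n) < dp[["stiff_neck"]])
  rti_grade <- ifelse(cough,
    sample(names(config$rti_grades), n, replace = TRUE,
           prob = config$rti_grades), "none")
  blood_stool <- diarrhoea & (stats::runif(n) < config$blood_given_diarrhoea)
  gi <- diarrhoea | vomiting
  dehydration <- ifelse(gi,
    sample(names(config$dehydration_grades), n, replace = TRUE,
           prob = config$dehydration_grades), NA_character_)

  cohort <- data.frame(
    child_id = sprintf("child_%04d", seq_len(n)),
    age_months = age, fever = fever, cough = cough, diarrhoea = diarrhoea,
    vomiting = vomiting, danger_drink = danger_drink,
    convulsions = convulsions, stiff_neck = stiff_neck,
    rti_grade = rti_grade, blood_stool = blood_stool,
    dehydration = dehydration, stringsAsFactors = FALSE
  )
  flags <- truth_flag_matrix(cohort)
  cohort$physician_triage <- vapply(seq_len(n), function(i) {
    triage(walk_flags(def, flags[i, ])$emitted, def)
  }, character(1))
  class(cohort) <- c("true_cohort", class(cohort))
  cohort
}

# n x 13 logical matrix of per-prompt underlying truth, columns PROMPT_KEYS.
# Severe respiratory truth surfaces via the breathing-inability question;
# the noisy-breathing question has no independent truth dimension.
truth_flag_matrix <- function(cohort) {
  cbind(
    q_danger_drink = cohort$danger_drink,
    q_convulsions = cohort$convulsions,
    q_fever = cohort$fever,
    q_stiff_neck = cohort$stiff_neck,
    q_cough = cohort$cough,
    q_breathing_inability = cohort$rti_grade == "severe",
    q_noisy_breathing = rep(FALSE, nrow(cohort)),
    q_fast_breathing = cohort$rti_grade == "moderate",
    q_diarrhoea = cohort$diarrhoea,
    q_blood_stool = cohort$blood_stool,
    q_vomiting = cohort$vomiting,
    q_lethargic = cohort$dehydration %in% "severe",
    q_sunken_eyes = cohort$dehydration %in% "some"
  )[, PROMPT_KEYS, drop = FALSE]
}

# per-prompt truth flags of one cohort row
truth_flags <- function(truth) {
  truth_flag_matrix(as.data.frame(truth, stringsAsFactors = FALSE))[1, ]
}

# deterministic tree walk under fixed per-prompt answer flags
walk_flags <- function(def, flags) {
  id <- def$entry
  nodes <- character()
  answers <- character()
  emitted <- character()
  while (!identical(id, TERMINAL)) {
    node <- def$nodes[[id]]
    ans <- if (flags[[node$prompt_id]]) ANSWER_YES else ANSWER_NO
    nodes <- c(nodes, id)
    answers <- c(answers, ans)
    em <- node$emissions[[ans]]
    if (length(em)) emitted <- union(emitted, em)
    id <- node$routes[[ans]]
  }
  list(nodes = nodes, answers = answers, emitted = emitted)
}

#' Guardian answers for one child under a reporting model
#'
#' Walks the decision tree as the guardian would experience it: at each
#' question the underlying true state is reported faithfully with the
#' model's per-question sensitivity (if truly present) or specificity (if
#' truly absent), and routing follows the \emph{reported} answer. Uses the
#' current RNG state; seed outside for reproducibility.
#'
#' @param truth one row of a [sample_cohort()] data frame.
#' @param model a [reporting_model()] covering every prompt on the path.
#' @inheritParams new_session
#' @return A list of class `answer_script`: `call_id`, `age_months`,
#'   `answers` (character vector in ask order).
#' @export
answers_from_truth <- function(truth, model, def = default_algorithm()) {
  stopifnot(inherits(model, "reporting_model"))
  flags <- truth_flags(truth)
  reported <- reported_flags(flags, model)
  structure(list(call_id = truth$child_id %||% NA_character_,
                 age_months = truth$age_months,
                 answers = walk_flags(def, reported)$answers),
            class = "answer_script")
}

# flip truth flags into reported flags under the model (one uniform draw
# per prompt)
reported_flags <- function(flags, model) {
  keys <- names(flags)
  miss <- setdiff(keys, intersect(names(model$sensitivity),
                                  names(model$specificity)))
  if (length(miss)) {
    stop("reporting model does not cover prompt(s): ", paste(miss, collapse = ", "))
  }
  u <- stats::runif(length(keys))
  stats::setNames(
    ifelse(flags, u < model$sensitivity[keys], u >= model$specificity[keys]),
    keys)
}

#' Simulate the validation study end to end
#'
#' Draws a cohort, lets a fraction of calls drop out mid-questionnaire,
#' runs every remaining guardian's (mis)reported answers through
#' [run_session()], and compares the tool's output against the
#' truth-derived physician standard: per-symptom detection statistics, the
#' 3x3 triage cross-tabulation and its summary statistics. Completed calls
#' that trigger no disease assessment are excluded from the triage
#' comparison (as the study excluded them).
#'
#' @param config a [cohort_config()].
#' @param model a [reporting_model()].
#' @inheritParams new_session
#' @param seed integer seed for all randomness (defaults to `config$seed`).
#' @return A list of class `study_simulation`:
#'   \describe{
#'     \item{cohort}{the sampled `true_cohort`.}
#'     \item{log}{the call log of all sessions (including abandoned).}
#'     \item{paired}{per-completed-call data frame of true and reported
#'       symptom flags plus tool and physician triage labels.}
#'     \item{symptom_stats}{per-symptom data frame: counts, recovered
#'       report sensitivity/specificity, agreement, kappa and its MC
#'       standard error (the kappa null/alternative SE at the simulated n).}
#'     \item{triage_table}{3x3 contingency table over evaluable calls.}
#'     \item{triage_stats}{agreement, kappa, under-triage rate, physician-A
#'       capture rate, and the dichotomized hospital/home statistics.}
#'     \item{counts}{n recruited / abandoned / completed / evaluable.}
#'   }
#' @export
simulate_study <- function(config, model = study_reporting_model(),
                           def = default_algorithm(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"), inherits(model, "reporting_model"))
  if (!is.null(seed)) set.seed(seed)
  cohort <- sample_cohort(config, def, seed = NULL)
  n <- config$n

  dropout <- stats::runif(n) < config$dropout_prob
  # one uniform draw per (child, question); the guardian misreports a truly
  # present state with prob 1 - sensitivity, an absent one with prob
  # 1 - specificity
  truth_mat <- truth_flag_matrix(cohort)
  u <- matrix(stats::runif(n * length(PROMPT_KEYS)), nrow = n)
  sens <- matrix(model$sensitivity[PROMPT_KEYS], n, length(PROMPT_KEYS),
                 byrow = TRUE)
  spec <- matrix(model$specificity[PROMPT_KEYS], n, length(PROMPT_KEYS),
                 byrow = TRUE)
  reported_mat <- (truth_mat & u < sens) | (!truth_mat & u >= spec)
  colnames(reported_mat) <- PROMPT_KEYS

  records <- vector("list", n)
  for (i in seq_len(n)) {
    answers <- walk_flags(def, reported_mat[i, ])$answers
    if (dropout[[i]]) {
      cut <- sample.int(length(answers), 1L)
      answers <- answers[seq_len(cut - 1L)]  # hangs up at question `cut`
    }
    records[[i]] <- run_session(def, answers, cohort$age_months[[i]],
                                call_id = cohort$child_id[[i]])
  }
  log <- call_log(records)

  completed <- which(vapply(records, function(r) r$status == "complete", logical(1)))
  reported_symptom <- function(r, node_ids) {
    any(r$answers$answer[r$answers$node %in% node_ids] == ANSWER_YES)
  }
  paired <- data.frame(
    call_id = cohort$child_id[completed],
    fever_true = cohort$fever[completed],
    cough_true = cohort$cough[completed],
    diarrhoea_true = cohort$diarrhoea[completed],
    vomiting_true = cohort$vomiting[completed],
    # extracted from the recorded answers, as the study read them off the
    # tool's call data (every complete path asks all four screens)
    fever_rep = vapply(records[completed], reported_symptom, logical(1),
                       node_ids = "fever"),
    cough_rep = vapply(records[completed], reported_symptom, logical(1),
                       node_ids = "cough"),
    diarrhoea_rep = vapply(records[completed], reported_symptom, logical(1),
                           node_ids = "diarrhoea"),
    vomiting_rep = vapply(records[completed], reported_symptom, logical(1),
                          node_ids = c("vomiting_gi", "vomiting_screen")),
    tool_triage = vapply(records[completed], `[[`, character(1),
                         "recommendation"),
    physician_triage = cohort$physician_triage[completed],
    stringsAsFactors = FALSE
  )

  symptom_stats <- do.call(rbind, lapply(
    c("fever", "cough", "diarrhoea", "vomiting"),
    function(s) {
      truth <- paired[[paste0(s, "_true")]]
      rep_ <- paired[[paste0(s, "_rep")]]
      tp <- sum(rep_ & truth); fn <- sum(!rep_ & truth)
      fp <- sum(rep_ & !truth); tn <- sum(!rep_ & !truth)
      ks <- cohens_kappa(confusion_table(tp, fn, fp, tn))
      m <- binary_metrics(tp, fn, fp, tn)
      # large-sample SE of the kappa estimate at the simulated size
      kappa_se <- sqrt(ks$po * (1 - ks$po) / ks$n) / (1 - ks$pe)
      data.frame(symptom = s, tp = tp, fn = fn, fp = fp, tn = tn,
                 prevalence = m$prevalence, sensitivity = m$sensitivity,
                 specificity = m$specificity, agreement = m$agreement,
                 kappa = ks$kappa, kappa_se = kappa_se,
                 stringsAsFactors = FALSE)
    }))

  evaluable <- paired[paired$tool_triage %in% c("A", "B", "C") &
                        paired$physician_triage %in% c("A", "B", "C"), ]
  triage_table <- tabulate_labels(evaluable$tool_triage,
                                  evaluable$physician_triage, c("A", "B", "C"))
  dich <- dichotomize_triage(triage_table)
  triage_stats <- if (nrow(evaluable) == 0L) {
    list(agreement = NA_real_, kappa = NULL, undertriage = NA_real_,
         capture_A = NA_real_, dichotomized_agreement = NA_real_,
         dichotomized_kappa = NULL)
  } else {
    list(
      agreement = percent_agreement(triage_table),
      kappa = cohens_kappa(triage_table),
      undertriage = undertriage_rate(triage_table),
      capture_A = capture_rate(triage_table, "A"),
      dichotomized_agreement = percent_agreement(dich),
      dichotomized_kappa = cohens_kappa(dich)
    )
  }

  structure(
    list(config = config, model = model, cohort = cohort, log = log,
         paired = paired, symptom_stats = symptom_stats,
         triage_table = triage_table, triage_stats = triage_stats,
         counts = c(recruited = n,
                    abandoned = sum(log$status == "abandoned"),
                    completed = length(completed),
                    evaluable = nrow(evaluable))),
    class = "study_simulation"
  )
}

#' @export
print.study_simulation <- function(x, ...) {
  cat("<study_simulation>\n")
  cat(sprintf("  recruited %d | abandoned %d | completed %d | evaluable %d\n",
              x$counts[["recruited"]], x$counts[["abandoned"]],
              x$counts[["completed"]], x$counts[["evaluable"]]))
  ss <- x$symptom_stats
  for (i in seq_len(nrow(ss))) {
    cat(sprintf("  %-10s kappa %.2f (report sens %.1f%%, spec %.1f%%)\n",
                ss$symptom[[i]], ss$kappa[[i]], 100 * ss$sensitivity[[i]],
                100 * ss$specificity[[i]]))
  }
  if (!is.null(x$triage_stats$kappa)) {
    cat(sprintf("  triage agreement %.1f%% | kappa %.2f | under-triage %.1f%%\n",
                100 * x$triage_stats$agreement, x$triage_stats$kappa$kappa,
                100 * x$triage_stats$undertriage))
  }
  invisible(x)
}
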