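# Session engine: walks a triage_algorithm, one dichotomous answer at a
# time, accumulating disease assessments until TERMINAL or abandonment.

#' Start a new call session
#'
#' @param def a [algorithm_definition()] object.
#' @param age_months child age in months; must fall inside the definition's
#'   eligible age window (default 1 month up to, not including, 15 years).
#'   Callers outside the window are rejected at session start: the algorithm
#'   was never designed for them.
#' @return A list of class `triage_session` with fields `age_months`,
#'   `current` (pending node id or `"TERMINAL"`), `answers` (two parallel
#'   character vectors `node` and `answer`), `emitted` (assessment ids so
#'   far) and `status` (`"in_progress"`, `"complete"` or `"abandoned"`).
#' @export
new_session <- function(def, age_months) {
  stopifnot(inherits(def, "triage_algorithm"))
  if (!is.numeric(age_months) || length(age_months) != 1L || is.na(age_months) ||
      age_months < def$age_limits[1] || age_months >= def$age_limits[2]) {
    stop(sprintf(
      "eligibility error: child age must be in [%g, %g) months, got %s",
      def$age_limits[1], def$age_limits[2], format(age_months)))
  }
  structure(
    list(age_months = as.numeric(age_months), current = def$entry,
         answers = list(node = character(), answer = character()),
         emitted = character(), status = "in_progress"),
    class = "triage_session"
  )
}

#' Next pending question of a session
#'
#' Deterministic function of the definition and the answers given so far.
#'
#' @inheritParams new_session
#' @param state a `triage_session`.
#' @return The pending [question_node()], or the string `"TERMINAL"` when
#'   the walk is finished.
#' @export
next_question <- function(def, state) {
  if (state$status != "in_progress") {
    stop("path error: session status is '", state$status, "', not in_progress")
  }
  if (identical(state$current, TERMINAL)) return(TERMINAL)
  def$nodes[[state$current]]
}

#' Record one answer
#'
#' Appends the answer, adds any disease assessments emitted by this
#' (question, answer) pair, and advances the walk. A no-response (silence
#' or hang-up) abandons the session without emitting anything.
#'
#' @inheritParams next_question
#' @param node_id id of the question being answered; must be the pending
#'   question (answers cannot be given out of order).
#' @param answer an element of [answer_alphabet()] or a raw keypad code
#'   understood by [normalize_answer()].
#' @return The updated `triage_session`.
#' @export
record_answer <- function(def, state, node_id, answer) {
  if (state$status != "in_progress") {
    stop("path error: session status is '", state$status, "', not in_progress")
  }
  if (!identical(node_id, state$current)) {
    stop("path error: pending question is '", state$current,
         "', cannot answer '", node_id, "'")
  }
  # canonical answers skip re-normalisation (hot path in simulations)
  if (!(is.character(answer) && length(answer) == 1L && !is.na(answer) &&
        answer %in% c(ANSWER_YES, ANSWER_NO, NO_RESPONSE))) {
    answer <- normalize_answer(answer)
  }
  state$answers$node <- c(state$answers$node, node_id)
  state$answers$answer <- c(state$answers$answer, answer)
  if (answer == NO_RESPONSE) {
    state$status <- "abandoned"
    return(state)
  }
  node <- def$nodes[[node_id]]
  state$emitted <- union(state$emitted, node$emissions[[answer]])
  state$current <- node$routes[[answer]]
  if (identical(state$current, TERMINAL)) state$status <- "complete"
  state
}

#' Triage a set of disease assessments
#'
#' The single treatment recommendation for a call is the maximum-severity
#' triage level over all registered disease assessments: the most
#' life-threatening condition wins. An empty set yields the sentinel
#' [TRIAGE_NONE] — the reported symptoms are not covered by the algorithm,
#' which is deliberately \emph{not} the same as recommending home care.
#'
#' @param assessments character vector of assessment ids.
#' @inheritParams new_session
#' @return A triage level code (`"A"`, `"B"`, `"C"`) or [TRIAGE_NONE].
#' @export
#' @examples
#' def <- default_algorithm()
#' triage("febrile_disease", def)
#' triage(c("mild_rti", "severe_rti", "febrile_disease"), def)
#' triage(character(), def)
triage <- function(assessments, def) {
  stopifnot(inherits(def, "triage_algorithm"))
  assessments <- unique(as.character(assessments))
  if (length(assessments) == 0L) return(TRIAGE_NONE)
  unknown <- setdiff(assessments, names(def$assessments))
  if (length(unknown)) {
    stop("catalogue error: unknown assessment id(s): ",
         paste(unknown, collapse = ", "))
  }
  codes <- vapply(def$assessments[assessments], function(a) a$triage, character(1))
  unname(codes[which.max(severity_rank(codes))])
}

#' Run a complete call session
#'
#' Drives a session from entry to terminal using a scripted answer vector or
#' an answer-providing function, and assembles the resulting call record.
#'
#' @inheritParams new_session
#' @param answers either a character vector of answer codes consumed in
#'   order (a vector that runs out before TERMINAL counts as a hang-up and
#'   abandons the call), or a function `f(node)` returning the answer to the
#'   pending [question_node()].
#' @param call_id optional identifier stored on the record.
#' @return A list of class `call_record` with fields `call_id`,
#'   `age_months`, `status`, `answers` (data frame of `node`, `answer`),
#'   `assessments` (character vector) and `recommendation` (a triage level
#'   code, [TRIAGE_NONE] for a completed call with no assessment, or `NA`
#'   for an abandoned call, which carries no recommendation).
#' @export
#' @examples
#' def <- default_algorithm()
#' # a guardian answering "no" to everything
#' run_session(def, rep("no", 15), age_months = 36)
run_session <- function(def, answers, age_months, call_id = NA_character_) {
  state <- new_session(def, age_months)
  provider <- if (is.function(answers)) {
    answers
  } else {
    script <- if (length(answers)) normalize_answer(as.character(answers)) else
      character()
    i <- 0L
    function(node) {
      i <<- i + 1L
      if (i > length(script)) NO_RESPONSE else script[[i]]
    }
  }
  while (state$status == "in_progress") {
    node <- next_question(def, state)
    if (identical(node, TERMINAL)) break
    state <- record_answer(def, state, node$id, provider(node))
  }
  as_call_record(def, state, call_id)
}

as_call_record <- function(def, state, call_id = NA_character_) {
  rec <- if (state$status == "complete") {
    triage(state$emitted, def)
  } else {
    NA_character_
  }
  structure(
    list(
      call_id = call_id, age_months = state$age_months,
      status = state$status,
      answers = data.frame(node = state$answers$node,
                           answer = state$answers$answer,
                           stringsAsFactors = FALSE),
      assessments = state$emitted,
      recommendation = rec
    ),
    class = "call_record"
  )
}

#' @export
print.call_record <- function(x, ...) {
  cat("<call_record>", if (!is.na(x$call_id)) x$call_id else "", "\n")
  cat("  age:", x$age_months, "months | status:", x$status, "|",
      nrow(x$answers), "answers\n")
  cat("  assessments:",
      if (length(x$assessments)) paste(x$assessments, collapse = ", ") else "(none)",
      "\n")
  cat("  recommendation:",
      if (is.na(x$recommendation)) "(abandoned)" else x$recommendation, "\n")
  invisible(x)
}

#' Replay a recorded answer path
#'
#' Recomputes the emitted assessments and final status from an ordered
#' `(node, answer)` path, verifying on the way that the path is a valid walk
#' of the definition. Used to check the replay-equivalence invariant: a
#' stored call record's assessments always equal the replay of its answers.
#'
#' @inheritParams new_session
#' @param answers a data frame with columns `node` and `answer`, as stored
#'   on a `call_record`.
#' @return A `triage_session` after replaying all answers.
#' @export
replay_session <- function(def, answers, age_months) {
  state <- new_session(def, age_months)
  for (i in seq_len(nrow(answers))) {
    state <- record_answer(def, state, answers$node[[i]], answers$answer[[i]])
  }
  state
}

#' Enumerate every complete answer path of a definition
#'
#' Exhaustively walks the (finite, acyclic) decision tree over the
#' dichotomous alphabet, returning every root-to-terminal answer vector with
#' the assessments emitted along it. The default tree has 960 such paths.
#'
#' @inheritParams new_session
#' @return A list of lists, each with `nodes`, `answers` (parallel character
#'   vectors) and `assessments`.
#' @export
enumerate_paths <- function(def) {
  stopifnot(inherits(def, "triage_algorithm"))
  out <- list()
  walk <- function(id, nodes, answers, emitted) {
    if (identical(id, TERMINAL)) {
      out[[length(out) + 1L]] <<- list(nodes = nodes, answers = answers,
                                       assessments = emitted)
      return(invisible(NULL))
    }
    node <- def$nodes[[id]]
    for (ans in c(ANSWER_YES, ANSWER_NO)) {
      walk(node$routes[[ans]], c(nodes, id), c(answers, ans),
           union(emitted, node$emissions[[ans]]))
    }
  }
  walk(def$entry, character(), character(), character())
  out
}
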