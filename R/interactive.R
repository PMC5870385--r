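#' Run an interactive call session on the terminal
#'
#' Simulates the hotline call flow: each question prompt is printed, the
#' caller answers by pressing 1 (yes) or 2 (no), and the call ends with the
#' advice string of the final recommendation plus any assessment-specific
#' extra advice. An unrecognised keypress is re-prompted up to `retry_limit`
#' times, after which the call is abandoned; an empty line (the caller
#' "hanging up") abandons immediately.
#'
#' @inheritParams new_session
#' @param age_months child age in months; if `NULL`, asked for first.
#' @param input a connection to read keypresses from (defaults to stdin; a
#'   [textConnection()] makes the function scriptable and testable).
#' @param output a connection or `""` for standard output.
#' @param prompts named prompt-text vector, see [default_prompts()].
#' @param retry_limit number of re-prompts allowed per question.
#' @param call_id optional identifier stored on the returned record.
#' @return The `call_record`, invisibly.
#' @export
#' @examples
#' def <- default_algorithm()
#' con <- textConnection(rep("2", 6)) # a guardian answering no to everything
#' rec <- run_interactive(def, age_months = 24, input = con)
#' close(con)
run_interactive <- function(def, age_months = NULL, input = stdin(),
                            output = stdout(), prompts = default_prompts(),
                            retry_limit = 2L, call_id = NA_character_) {
  say <- function(...) writeLines(paste0(...), con = output)
  ask_line <- function() {
    x <- readLines(input, n = 1L)
    if (length(x) == 0L) "" else trimws(x)
  }

  say("== Child illness triage hotline ==")
  say(attr(prompts, "answer_help") %||% "Press 1 for yes, press 2 for no.")

  if (is.null(age_months)) {
    say(prompts[["q_age"]] %||% "How old is your child, in months?")
    age_months <- suppressWarnings(as.numeric(ask_line()))
  }
  state <- new_session(def, age_months)  # eligibility checked here

  take_answer <- function(node) {
    tries <- 0L
    repeat {
      raw <- ask_line()
      ans <- tryCatch(normalize_answer(raw), error = function(e) NA_character_)
      if (!is.na(ans)) return(ans)
      tries <- tries + 1L
      if (tries > retry_limit) return(NO_RESPONSE)
      say("Sorry, I did not understand. ",
          attr(prompts, "answer_help") %||% "Press 1 for yes, press 2 for no.")
    }
  }

  while (state$status == "in_progress") {
    node <- next_question(def, state)
    if (identical(node, TERMINAL)) break
    say(prompts[[node$prompt_id]] %||% node$prompt_id)
    state <- record_answer(def, state, node$id, take_answer(node))
  }
  rec <- as_call_record(def, state, call_id)

  if (rec$status == "abandoned") {
    say("Call ended before all questions were answered. ",
        "Please call again, or seek medical care if you are worried.")
  } else {
    say(triage_advice(rec$recommendation))
    for (a in rec$assessments) {
      for (tip in def$assessments[[a]]$extra_advice) say(tip)
    }
  }
  invisible(rec)
}
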