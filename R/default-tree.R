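# The shipped default algorithm: a reconstruction of an IMCI-derived triage
# flow reduced to ask-only dichotomous questions a lay guardian can answer
# over the phone. All reconstruction choices live in the shipped definition
# file (inst/extdata/imci_default.json), not in code, so a corrected
# transcription can replace them without touching the engine.

#' The default IMCI-derived triage algorithm
#'
#' Loads the triage decision tree shipped with the package. The flow is:
#' two danger-sign questions (inability to drink/breastfeed; convulsions or
#' unconsciousness), then the four symptom screens fever, cough, diarrhoea
#' and vomiting. A confirmed symptom opens its severity block: stiff neck
#' after fever; three respiratory severity questions after cough (a severe
#' finding short-circuits the block, so exactly one respiratory grade is
#' emitted); blood in stool after diarrhoea; and two dehydration questions
#' whenever diarrhoea or vomiting is confirmed. Eleven disease assessments
#' can be emitted, each tied to one triage level via the A/B/C catalogue.
#'
#' No question requires physical examination or measurement — no breath
#' counting, no thermometer reading, no chest inspection; every node carries
#' the `ask_only` flag.
#'
#' @return A `triage_algorithm` (14 nodes, 11 assessments, longest path 13
#'   questions).
#' @seealso [validate_algorithm()], [run_session()], [default_prompts()]
#' @export
#' @examples
#' def <- default_algorithm()
#' def
#' is_valid(validate_algorithm(def))
default_algorithm <- function() {
  path <- system.file("extdata", "imci_default.json", package = "ivrtriage",
                      mustWork = TRUE)
  read_algorithm(path)
}

#' English reference text for the default prompts
#'
#' Prompt ids are abstract keys (in deployment they name audio recordings in
#' the local language); this table carries the English reference wording
#' used by the interactive front-end.
#'
#' @param locale locale key; only `"en"` is shipped.
#' @return Named character vector mapping `prompt_id` to question text, with
#'   an `"answer_help"` attribute holding the keypad instruction.
#' @export
default_prompts <- function(locale = "en") {
  path <- system.file("extdata", paste0("prompts_", locale, ".json"),
                      package = "ivrtriage")
  if (!nzchar(path)) stop("no prompt file shipped for locale '", locale, "'")
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  prompts <- unlist(raw$prompts)
  attr(prompts, "answer_help") <- raw$answer_help
  prompts
}
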