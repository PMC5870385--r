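# Independent engine oracle: re-derives every complete answer path straight
# from the raw definition file (no engine code) and looks up the
# maximum-severity recommendation with an independently coded table.

oracle_paths <- function() {
  raw <- jsonlite::fromJSON(
    system.file("extdata", "imci_default.json", package = "ivrtriage"),
    simplifyVector = FALSE)
  nodes <- setNames(raw$nodes, vapply(raw$nodes, `[[`, character(1), "id"))
  acc <- list()
  recurse <- function(id, answers, emitted) {
    if (identical(id, "TERMINAL")) {
      acc[[length(acc) + 1L]] <<- list(answers = answers, emitted = emitted)
      return(invisible(NULL))
    }
    n <- nodes[[id]]
    for (ans in c("yes", "no")) {
      recurse(n$routes[[ans]], c(answers, ans),
              unique(c(emitted, unlist(n$emissions[[ans]]))))
    }
  }
  recurse(raw$entry, character(), character())
  acc
}

# severity lookup coded independently from the published A/B/C grouping
oracle_recommendation <- function(emitted) {
  level <- c(
    inability_to_drink = "A", neurological_emergency = "A",
    severe_febrile_disease = "A", severe_rti = "A",
    gi_severe_dehydration = "A",
    febrile_disease = "B", moderate_rti = "B", gi_some_dehydration = "B",
    dysentery = "B",
    mild_rti = "C", gi_no_dehydration = "C"
  )
  if (length(emitted) == 0L) return("NONE_APPLICABLE")
  got <- level[emitted]
  if ("A" %in% got) "A" else if ("B" %in% got) "B" else "C"
}
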