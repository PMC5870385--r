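# Shared fixtures built in code.

# Published 3x3 triage cross-tabulation (tool rows, physician columns).
table4_counts <- function() {
  matrix(c(42L, 121L, 8L,
           6L, 47L, 2L,
           0L, 7L, 4L),
         nrow = 3, byrow = TRUE,
         dimnames = list(tool = c("A", "B", "C"),
                         physician = c("A", "B", "C")))
}

# Integer 2x2 cells (tp, fn, fp, tn) implied by the published rounded
# summaries; frozen from an exhaustive search over all integer tables with
# n = 237 (each is the unique admissible solution).
reconstructed_cells <- function() {
  list(
    fever = c(151L, 16L, 23L, 47L),
    cough = c(119L, 11L, 31L, 76L),
    diarrhoea = c(37L, 6L, 31L, 163L),
    vomiting = c(39L, 19L, 37L, 142L),
    febrile_disease = c(139L, 28L, 22L, 48L)
  )
}

# A tiny two-question tree used by unit tests: fever -> cough -> end.
toy_algorithm <- function(question_cap = 15) {
  algorithm_definition(
    nodes = list(
      question_node("q_fever", block = "fever", yes = "q_cough", no = "q_cough",
                    emit_yes = "febrile"),
      question_node("q_cough", block = "rti",
                    emit_yes = "mild_cough", emit_no = "well")
    ),
    assessments = list(
      disease_assessment("febrile", "Febrile disease", "B"),
      disease_assessment("mild_cough", "Mild cough", "C"),
      disease_assessment("well", "No findings", "C")
    ),
    entry = "q_fever", question_cap = question_cap
  )
}

# Scripted answers that drive the default tree to a single target
# assessment, all other questions answered no.
all_no_except <- function(def, yes_nodes) {
  function(node) if (node$id %in% yes_nodes) "yes" else "no"
}
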