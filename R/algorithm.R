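#' @keywords internal
"_PACKAGE"

# The answer alphabet of the dichotomous IVR questions. Keypad code 1 maps
# to "yes", 2 to "no"; silence or hang-up is the explicit NO_RESPONSE marker.
ANSWER_YES <- "yes"
ANSWER_NO <- "no"
NO_RESPONSE <- "no_response"
TERMINAL <- "TERMINAL"

#' Answer alphabet
#'
#' @return Character vector of the three legal answers: `"yes"`, `"no"` and
#'   the explicit no-response marker `"no_response"` (silence or hang-up).
#' @export
answer_alphabet <- function() c(ANSWER_YES, ANSWER_NO, NO_RESPONSE)

#' Normalise an answer code
#'
#' Maps IVR keypad codes and synonyms onto the canonical answer alphabet:
#' `1`/`y`/`yes` become `"yes"`, `2`/`n`/`no` become `"no"`, and `NA`, the
#' empty string, `0` or `"no_response"` become the no-response marker.
#'
#' @param x character (or numeric) vector of raw answer codes.
#' @return character vector over [answer_alphabet()].
#' @export
#' @examples
#' normalize_answer(c("1", "2", "yes", ""))
normalize_answer <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- ifelse(is.na(x) | x %in% c("", "0", "no_response", "timeout"), NO_RESPONSE,
    ifelse(x %in% c("1", "y", "yes"), ANSWER_YES,
      ifelse(x %in% c("2", "n", "no"), ANSWER_NO, NA_character_)))
  if (anyNA(out)) {
    stop("unknown answer code(s): ", paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

#' Construct a question node
#'
#' A node of the triage decision tree: one dichotomous question, its routing
#' and the disease assessments it emits. Routing is memoryless: the next
#' node depends only on this node and the answer given.
#'
#' @param id unique node identifier.
#' @param prompt_id key of the audio/text prompt played for this question
#'   (several nodes may share a prompt, e.g. the same question reached along
#'   different paths). Defaults to `id`.
#' @param block label of the contextually related question group the node
#'   belongs to (danger signs, fever, respiratory, gastrointestinal, ...).
#' @param yes,no id of the next node when the caller answers yes / no, or
#'   `"TERMINAL"` to end the call flow.
#' @param emit_yes,emit_no character vectors of disease-assessment ids
#'   emitted on a yes / no answer.
#' @param ask_only flag asserting that the question can be answered by a lay
#'   guardian without any physical examination or measurement. All shipped
#'   questions are ask-only.
#' @return A list of class `question_node`.
#' @export
question_node <- function(id, prompt_id = id, block = "general",
                          yes = TERMINAL, no = TERMINAL,
                          emit_yes = character(), emit_no = character(),
                          ask_only = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(
    list(
      id = id, prompt_id = prompt_id, block = block,
      routes = list(yes = yes, no = no),
      emissions = list(yes = as.character(emit_yes), no = as.character(emit_no)),
      ask_only = isTRUE(ask_only)
    ),
    class = "question_node"
  )
}

#' Construct a disease assessment
#'
#' A named illness category the algorithm can register, tied to exactly one
#' triage level and optionally to extra caller advice (e.g. oral rehydration
#' salts for gastrointestinal infection).
#'
#' @param id unique assessment identifier.
#' @param display_name human-readable name.
#' @param triage triage level code, one of `"A"`, `"B"`, `"C"`.
#' @param extra_advice character vector of additional advice strings.
#' @return A list of class `disease_assessment`.
#' @export
disease_assessment <- function(id, display_name = id, triage,
                               extra_advice = character()) {
  stopifnot(is.character(id), length(id) == 1L)
  if (!triage %in% triage_levels()$code) {
    stop("triage level must be one of A, B, C; got ", triage)
  }
  structure(
    list(id = id, display_name = display_name, triage = triage,
         extra_advice = as.character(extra_advice)),
    class = "disease_assessment"
  )
}

#' Construct a triage algorithm definition
#'
#' Bundles the question nodes, the disease-assessment catalogue, the entry
#' node and session-level constraints into a validated decision-tree
#' definition.
#'
#' @param nodes list of [question_node()] objects.
#' @param assessments list of [disease_assessment()] objects.
#' @param entry id of the first question asked.
#' @param version free-form version string.
#' @param question_cap maximum number of questions any path may ask. The
#'   default of 15 reflects the usability ceiling for an automated phone
#'   call: longer interrogations protract the call and lose the caller.
#' @param age_limits two-element numeric vector, minimum (inclusive) and
#'   maximum (exclusive) eligible child age in months. Defaults to 1 month
#'   up to (not including) 15 years.
#' @return A list of class `triage_algorithm`.
#' @seealso [validate_algorithm()], [default_algorithm()]
#' @export
algorithm_definition <- function(nodes, assessments, entry,
                                 version = "0.0", question_cap = 15L,
                                 age_limits = c(1, 180)) {
  node_ids <- vapply(nodes, function(n) n$id, character(1))
  if (anyDuplicated(node_ids)) stop("duplicate node ids")
  names(nodes) <- node_ids
  asmt_ids <- vapply(assessments, function(a) a$id, character(1))
  if (anyDuplicated(asmt_ids)) stop("duplicate assessment ids")
  names(assessments) <- asmt_ids
  stopifnot(length(age_limits) == 2L, age_limits[1] < age_limits[2])
  structure(
    list(
      version = as.character(version), entry = entry,
      question_cap = as.integer(question_cap),
      age_limits = as.numeric(age_limits),
      nodes = nodes, assessments = assessments
    ),
    class = "triage_algorithm"
  )
}

#' @export
print.triage_algorithm <- function(x, ...) {
  cat("<triage_algorithm> version", x$version, "\n")
  cat(" ", length(x$nodes), "question nodes,", length(x$assessments),
      "disease assessments\n")
  cat("  entry:", x$entry, " question cap:", x$question_cap, "\n")
  cat("  eligible age: [", x$age_limits[1], ",", x$age_limits[2], ") months\n")
  invisible(x)
}

#' Validate an algorithm definition
#'
#' Checks the structural soundness of a decision-tree definition:
#' \itemize{
#'   \item \emph{integrity} — the entry node exists, every route target is a
#'     known node or `TERMINAL`, every emitted assessment id is in the
#'     catalogue;
#'   \item \emph{acyclicity} — no directed cycle in the routing graph;
#'   \item \emph{bounded length} — the longest root-to-terminal path asks at
#'     most `question_cap` questions;
#'   \item \emph{reachability} — every assessment in the catalogue is
#'     emitted by at least one node reachable from the entry.
#' }
#' Violations are returned as data, not raised as errors, so that a
#' definition file can be linted in one pass.
#'
#' @param def a [algorithm_definition()] object.
#' @return A data frame of class `validation_report` with columns `rule`,
#'   `where` and `message`; zero rows if and only if the definition is valid
#'   (see [is_valid()]).
#' @export
validate_algorithm <- function(def) {
  stopifnot(inherits(def, "triage_algorithm"))
  probs <- list()
  add <- function(rule, where, message) {
    probs[[length(probs) + 1L]] <<- data.frame(
      rule = rule, where = where, message = message, stringsAsFactors = FALSE)
  }
  node_ids <- names(def$nodes)
  asmt_ids <- names(def$assessments)

  if (!def$entry %in% node_ids) {
    add("integrity", def$entry, "entry node is not defined")
  }
  for (n in def$nodes) {
    for (ans in c("yes", "no")) {
      tgt <- n$routes[[ans]]
      if (!identical(tgt, TERMINAL) && !tgt %in% node_ids) {
        add("integrity", n$id,
            sprintf("route on '%s' targets unknown node '%s'", ans, tgt))
      }
      bad <- setdiff(n$emissions[[ans]], asmt_ids)
      if (length(bad)) {
        add("integrity", n$id,
            sprintf("emission on '%s' names unknown assessment(s): %s",
                    ans, paste(bad, collapse = ", ")))
      }
    }
  }
  if (length(probs)) {
    rep <- do.call(rbind, probs)
    class(rep) <- c("validation_report", "data.frame")
    return(rep)  # graph checks need an intact graph
  }

  # depth-first search from the entry: cycle detection, reachability and
  # longest path in one pass (colour marking; depth memoised on the DAG)
  colour <- stats::setNames(rep("white", length(node_ids)), node_ids)
  depth <- stats::setNames(rep(NA_real_, length(node_ids)), node_ids)
  cyclic <- FALSE
  visit <- function(id) {
    if (colour[[id]] == "grey") {
      cyclic <<- TRUE
      return(0)
    }
    if (colour[[id]] == "black") return(depth[[id]])
    colour[[id]] <<- "grey"
    d <- 0
    for (ans in c("yes", "no")) {
      tgt <- def$nodes[[id]]$routes[[ans]]
      if (!identical(tgt, TERMINAL)) d <- max(d, visit(tgt))
      if (cyclic) break
    }
    colour[[id]] <<- "black"
    depth[[id]] <<- 1 + d
    1 + d
  }
  max_depth <- if (def$entry %in% node_ids) visit(def$entry) else 0

  if (cyclic) {
    add("acyclicity", def$entry, "routing graph contains a directed cycle")
  } else {
    if (max_depth > def$question_cap) {
      add("question_cap", def$entry,
          sprintf("longest path asks %d questions, cap is %d",
                  max_depth, def$question_cap))
    }
    reachable <- node_ids[colour == "black"]
    emitted <- unique(unlist(lapply(def$nodes[reachable],
                                    function(n) unlist(n$emissions))))
    for (a in setdiff(asmt_ids, emitted)) {
      add("reachability", a, "assessment is never emitted on any reachable path")
    }
  }

  rep <- if (length(probs)) do.call(rbind, probs) else
    data.frame(rule = character(), where = character(), message = character(),
               stringsAsFactors = FALSE)
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' @rdname validate_algorithm
#' @param report a `validation_report`.
#' @return `is_valid()` returns `TRUE` if the report is empty.
#' @export
is_valid <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  nrow(report) == 0L
}

#' Read / write an algorithm definition file
#'
#' Definitions are stored as structured text (JSON or YAML, chosen by file
#' extension) with top-level keys `version`, `entry`, `question_cap`,
#' `age_limits`, `nodes` and `assessments`. The round trip
#' `read_algorithm(write_algorithm(def))` is lossless.
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_algorithm()` returns a `triage_algorithm`.
#' @export
read_algorithm <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  need <- c("version", "entry", "nodes", "assessments")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("definition file lacks required key(s): ", paste(miss, collapse = ", "))
  }
  nodes <- lapply(raw$nodes, function(n) {
    question_node(
      id = n$id, prompt_id = n$prompt_id %||% n$id,
      block = n$block %||% "general",
      yes = n$routes$yes %||% TERMINAL, no = n$routes$no %||% TERMINAL,
      emit_yes = unlist(n$emissions$yes) %||% character(),
      emit_no = unlist(n$emissions$no) %||% character(),
      ask_only = n$ask_only %||% TRUE
    )
  })
  assessments <- lapply(raw$assessments, function(a) {
    disease_assessment(
      id = a$id, display_name = a$display_name %||% a$id, triage = a$triage,
      extra_advice = unlist(a$extra_advice) %||% character()
    )
  })
  algorithm_definition(
    nodes = nodes, assessments = assessments, entry = raw$entry,
    version = raw$version, question_cap = raw$question_cap %||% 15L,
    age_limits = unlist(raw$age_limits) %||% c(1, 180)
  )
}

#' @rdname read_algorithm
#' @param def a `triage_algorithm`.
#' @return `write_algorithm()` returns `path`, invisibly.
#' @export
write_algorithm <- function(def, path) {
  stopifnot(inherits(def, "triage_algorithm"))
  raw <- list(
    version = def$version,
    entry = def$entry,
    question_cap = def$question_cap,
    age_limits = def$age_limits,
    nodes = lapply(unname(def$nodes), function(n) {
      list(id = n$id, prompt_id = n$prompt_id, block = n$block,
           routes = n$routes,
           emissions = lapply(n$emissions, as.list),
           ask_only = n$ask_only)
    }),
    assessments = lapply(unname(def$assessments), function(a) {
      list(id = a$id, display_name = a$display_name, triage = a$triage,
           extra_advice = as.list(a$extra_advice))
    })
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(raw, path)
  } else {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(path)
}
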