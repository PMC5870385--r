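# Call-log CSV dialect: comma-separated, quoted strings, UTF-8, LF endings.
# One row per session:
#   call_id, age_months, status, answers, assessments, recommendation
# `answers` is a pipe-separated list of node:answer pairs in call order;
# `assessments` a pipe-separated list of assessment ids; an abandoned call
# has an empty recommendation.

#' Convert call records to a call-log data frame
#'
#' @param records a list of `call_record` objects (or a single one).
#' @return A data frame with one row per call and columns `call_id`,
#'   `age_months`, `status`, `answers`, `assessments`, `recommendation`.
#' @export
call_log <- function(records) {
  if (inherits(records, "call_record")) records <- list(records)
  rows <- lapply(records, function(r) {
    data.frame(
      call_id = if (is.na(r$call_id)) "" else r$call_id,
      age_months = r$age_months,
      status = r$status,
      answers = paste(paste(r$answers$node, r$answers$answer, sep = ":"),
                      collapse = "|"),
      assessments = paste(r$assessments, collapse = "|"),
      recommendation = if (is.na(r$recommendation)) "" else r$recommendation,
      stringsAsFactors = FALSE
    )
  })
  if (length(rows)) do.call(rbind, rows) else empty_call_log()
}

empty_call_log <- function() {
  data.frame(call_id = character(), age_months = numeric(),
             status = character(), answers = character(),
             assessments = character(), recommendation = character(),
             stringsAsFactors = FALSE)
}

#' Write / read a call log
#'
#' @param log a call-log data frame from [call_log()] or [run_batch()].
#' @param path CSV file path.
#' @return `read_call_log()` returns the call-log data frame; the write/read
#'   round trip is lossless.
#' @export
write_call_log <- function(log, path) {
  stopifnot(all(names(empty_call_log()) %in% names(log)))
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(log, con, row.names = FALSE, eol = "\n", na = "")
  invisible(path)
}

#' @rdname write_call_log
#' @export
read_call_log <- function(path) {
  log <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(call_id = "character",
                                        age_months = "numeric",
                                        status = "character",
                                        answers = "character",
                                        assessments = "character",
                                        recommendation = "character"),
                         encoding = "UTF-8")
  miss <- setdiff(names(empty_call_log()), names(log))
  if (length(miss)) stop("call log lacks column(s): ", paste(miss, collapse = ", "))
  log$recommendation[is.na(log$recommendation)] <- ""
  log$answers[is.na(log$answers)] <- ""
  log$assessments[is.na(log$assessments)] <- ""
  log
}

#' Extract the answer vector from a call-log row
#'
#' @param log_row one row of a call-log data frame.
#' @return Character vector of answers, in call order.
#' @export
log_answers <- function(log_row) {
  if (!nzchar(log_row$answers)) return(character())
  pairs <- strsplit(log_row$answers, "|", fixed = TRUE)[[1]]
  sub("^[^:]*:", "", pairs)
}

#' Read an answer-script file
#'
#' Scripts are CSVs with columns `call_id`, `age_months` and `answers`
#' (pipe-separated answer codes, e.g. `"1|2|2|1"`). Malformed rows are
#' reported with their line number and skipped; the run continues.
#'
#' @param path CSV file path.
#' @return A data frame `call_id`, `age_months`, `answers` (list column of
#'   character vectors), with an attribute `problems` (data frame of skipped
#'   line numbers and reasons).
#' @export
read_answer_scripts <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("call_id", "age_months", "answers")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("script file lacks column(s): ", paste(miss, collapse = ", "))
  problems <- list()
  keep <- logical(nrow(raw))
  answers <- vector("list", nrow(raw))
  age <- rep(NA_real_, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    line <- i + 1L  # header is line 1
    age_i <- suppressWarnings(as.numeric(raw$age_months[[i]]))
    codes <- strsplit(raw$answers[[i]], "|", fixed = TRUE)[[1]]
    ok <- TRUE
    if (is.na(age_i)) {
      problems[[length(problems) + 1L]] <-
        data.frame(line = line, reason = "age_months is not a number")
      ok <- FALSE
    }
    if (ok && length(codes)) {
      norm <- tryCatch(normalize_answer(codes), error = function(e) NULL)
      if (is.null(norm)) {
        problems[[length(problems) + 1L]] <-
          data.frame(line = line, reason = "unknown answer code")
        ok <- FALSE
      } else {
        codes <- norm
      }
    }
    keep[[i]] <- ok
    answers[[i]] <- codes
    age[[i]] <- age_i
  }
  out <- data.frame(call_id = raw$call_id, age_months = age,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out$answers <- answers[keep]
  out$.line <- (seq_len(nrow(raw)) + 1L)[keep]  # original file line numbers
  attr(out, "problems") <- if (length(problems)) do.call(rbind, problems) else
    data.frame(line = integer(), reason = character())
  out
}

#' Run a batch of scripted call sessions
#'
#' Replays every answer script through [run_session()] and returns (and
#' optionally writes) the resulting call log. Scripts that run out of
#' answers before the walk reaches TERMINAL are flagged `abandoned`, exactly
#' as an interactive hang-up would be. Deterministic: identical scripts give
#' identical logs.
#'
#' @inheritParams new_session
#' @param scripts a path to an answer-script CSV (see
#'   [read_answer_scripts()]) or an equivalent data frame.
#' @param out optional path; when given, the log is written there as CSV.
#' @return The call-log data frame, invisibly carrying the `problems`
#'   attribute of the script file.
#' @export
run_batch <- function(def, scripts, out = NULL) {
  if (is.character(scripts)) scripts <- read_answer_scripts(scripts)
  problems <- attr(scripts, "problems") %||%
    data.frame(line = integer(), reason = character())
  records <- list()
  for (i in seq_len(nrow(scripts))) {
    rec <- tryCatch(
      run_session(def, scripts$answers[[i]], scripts$age_months[[i]],
                  call_id = scripts$call_id[[i]]),
      error = function(e) e)
    if (inherits(rec, "error")) {
      line <- if (!is.null(scripts$.line)) scripts$.line[[i]] else i + 1L
      problems <- rbind(problems,
                        data.frame(line = line, reason = conditionMessage(rec)))
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  log <- call_log(records)
  attr(log, "problems") <- problems
  if (!is.null(out)) write_call_log(log, out)
  log
}
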