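# Shipped transcriptions of the hospital validation study's published
# summary tables: per-symptom detection statistics, per-assessment
# statistics, and the 3x3 triage cross-tabulation (n = 237 completed,
# analysable calls).

#' Published evaluation-study summary tables
#'
#' Loads the summary statistics of the hospital validation study shipped
#' with the package:
#' \describe{
#'   \item{`"symptoms"`}{per-symptom detection statistics (fever, cough,
#'     diarrhoea, vomiting): agreement, kappa, p-value, sensitivity,
#'     specificity, PPV, NPV and physician prevalence, all as printed
#'     percentages / 2 d.p. kappas.}
#'   \item{`"assessments"`}{the same statistics for the eleven disease
#'     assessments, grouped by triage level; rows the physicians never
#'     diagnosed are `n/a`.}
#'   \item{`"triage"`}{the 3x3 tool-versus-physician triage counts.}
#' }
#'
#' @param which one of `"symptoms"`, `"assessments"`, `"triage"`.
#' @return A data frame; numeric columns are numeric, the `p_value` column
#'   stays character because values below the printing threshold appear as
#'   `"<0.01"`, and `n/a` entries are `NA`.
#' @seealso [study_triage_table()] for the triage counts as a matrix.
#' @export
#' @examples
#' study_table("symptoms")
study_table <- function(which = c("symptoms", "assessments", "triage")) {
  which <- match.arg(which)
  file <- switch(which,
    symptoms = "table2_symptoms.csv",
    assessments = "table3_assessments.csv",
    triage = "table4_triage.csv"
  )
  path <- system.file("extdata", file, package = "ivrtriage", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  for (col in setdiff(names(raw), c("symptom", "assessment", "triage", "tool",
                                    "p_value"))) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  if ("p_value" %in% names(raw)) raw$p_value[raw$p_value == "n/a"] <- NA
  raw
}

#' The study's triage cross-tabulation as a contingency table
#'
#' @return The 3x3 integer matrix of tool (rows) versus physician (columns)
#'   triage recommendations over the 237 analysed calls, as a
#'   `contingency_table`.
#' @export
#' @examples
#' tab <- study_triage_table()
#' percent_agreement(tab)
#' cohens_kappa(tab)$kappa
study_triage_table <- function() {
  raw <- study_table("triage")
  out <- as.matrix(raw[, c("physician_A", "physician_B", "physician_C")])
  storage.mode(out) <- "integer"
  dimnames(out) <- list(tool = raw$tool, physician = c("A", "B", "C"))
  class(out) <- c("contingency_table", class(out))
  out
}

#' Reconstruct every publishable 2x2 table of the study
#'
#' Applies [reconstruct_confusion()] to each row of the shipped symptom and
#' assessment tables that has a defined 2x2 (the physicians never diagnosed
#' two of the eleven assessments, so 4 symptom rows + 9 assessment rows are
#' reconstructable).
#'
#' @return A data frame with one row per reconstructed condition: `item`,
#'   `source` (`"symptoms"` or `"assessments"`), cells `tp`, `fn`, `fp`,
#'   `tn`, the implied `kappa` (2 d.p. recomputed from the cells), implied
#'   `agreement_pct`, `ppv_pct`, `npv_pct`, `p_value` (one-sided), and the
#'   printed values for comparison.
#' @export
reconstruct_study_tables <- function() {
  one <- function(item, source, row) {
    rc <- reconstruct_confusion(
      n = 237, prevalence = row$prevalence_pct,
      sensitivity = row$sensitivity_pct, specificity = row$specificity_pct,
      agreement = row$agreement_pct, ppv = row$ppv_pct, npv = row$npv_pct
    )
    ks <- cohens_kappa(confusion_table(rc$tp, rc$fn, rc$fp, rc$tn))
    data.frame(
      item = item, source = source,
      tp = rc$tp, fn = rc$fn, fp = rc$fp, tn = rc$tn,
      kappa = ks$kappa, p_value = ks$p_value,
      agreement_pct = 100 * rc$metrics$agreement,
      ppv_pct = 100 * rc$metrics$ppv, npv_pct = 100 * rc$metrics$npv,
      printed_kappa = row$kappa, printed_agreement_pct = row$agreement_pct,
      printed_sensitivity_pct = row$sensitivity_pct,
      printed_specificity_pct = row$specificity_pct,
      printed_ppv_pct = row$ppv_pct, printed_npv_pct = row$npv_pct,
      exact = rc$exact,
      stringsAsFactors = FALSE
    )
  }
  t2 <- study_table("symptoms")
  t3 <- study_table("assessments")
  t3 <- t3[!is.na(t3$agreement_pct), ]
  rows <- c(
    lapply(seq_len(nrow(t2)), function(i) one(t2$symptom[[i]], "symptoms", t2[i, ])),
    lapply(seq_len(nrow(t3)), function(i) one(t3$assessment[[i]], "assessments", t3[i, ]))
  )
  do.call(rbind, rows)
}
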