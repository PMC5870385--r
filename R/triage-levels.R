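#' Triage levels A/B/C
#'
#' The three triage levels used throughout the package, in decreasing order
#' of severity:
#' \describe{
#'   \item{A}{requiring emergency treatment (severity rank 3)}
#'   \item{B}{requiring causal (etiologic) treatment within 24 hours
#'     (severity rank 2)}
#'   \item{C}{requiring home care (severity rank 1)}
#' }
#' The advice strings are the caller-facing messages played at the end of a
#' completed call.
#'
#' @return A data frame with columns `code`, `severity_rank`, `label` and
#'   `advice`, one row per level, ordered A, B, C.
#' @export
#' @examples
#' triage_levels()
triage_levels <- function() {
  data.frame(
    code = c("A", "B", "C"),
    severity_rank = c(3L, 2L, 1L),
    label = c(
      "Requiring emergency treatment",
      "Requiring etiologic treatment",
      "Requiring home care"
    ),
    advice = c(
      "Take your child to the nearest hospital immediately!",
      "Take your child to the nearest hospital within 24 h!",
      "Treat your child at home and assess disease progression carefully!"
    ),
    stringsAsFactors = FALSE
  )
}

#' @rdname triage_levels
#' @format `TRIAGE_NONE` is the sentinel recommendation for a completed call
#'   in which no disease assessment was emitted. The engine deliberately does
#'   not map such calls to home care (level C): the symptoms are simply not
#'   covered by the algorithm.
#' @export
TRIAGE_NONE <- "NONE_APPLICABLE"

#' @rdname triage_levels
#' @param code a vector of level codes (`"A"`, `"B"`, `"C"`) or
#'   `TRIAGE_NONE`.
#' @return `triage_advice()` returns the advice string for each code.
#' @export
triage_advice <- function(code) {
  lv <- triage_levels()
  out <- lv$advice[match(code, lv$code)]
  out[code == TRIAGE_NONE] <- paste(
    "The symptoms you reported are not covered by this service.",
    "Please seek medical care if you are worried about your child."
  )
  if (anyNA(out)) stop("unknown triage code: ", paste(code[is.na(out)], collapse = ", "))
  out
}

#' @rdname triage_levels
#' @return `severity_rank()` returns the integer severity rank (A=3, B=2,
#'   C=1) of each code.
#' @export
severity_rank <- function(code) {
  lv <- triage_levels()
  r <- lv$severity_rank[match(code, lv$code)]
  if (anyNA(r)) stop("unknown triage code: ", paste(code[is.na(r)], collapse = ", "))
  r
}

#' Landis-Koch verbal interpretation of a kappa value
#'
#' Maps Cohen's kappa onto the conventional agreement bands:
#' below 0 "poor"; 0 to 0.20 "slight"; 0.21 to 0.40 "fair"; 0.41 to 0.60
#' "moderate"; 0.61 to 0.80 "substantial"; above 0.80 "almost perfect".
#'
#' @param kappa numeric vector of kappa values in \[-1, 1\].
#' @return character vector of band labels (`NA` for `NA` input).
#' @export
#' @examples
#' landis_koch_band(c(-0.2, 0.11, 0.28, 0.51, 0.64, 0.95))
landis_koch_band <- function(kappa) {
  stopifnot(is.numeric(kappa))
  if (any(kappa < -1 - 1e-12 | kappa > 1 + 1e-12, na.rm = TRUE)) {
    stop("kappa must lie in [-1, 1]")
  }
  ifelse(is.na(kappa), NA_character_,
    ifelse(kappa < 0, "poor",
      ifelse(kappa <= 0.20, "slight",
        ifelse(kappa <= 0.40, "fair",
          ifelse(kappa <= 0.60, "moderate",
            ifelse(kappa <= 0.80, "substantial", "almost perfect"))))))
}
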