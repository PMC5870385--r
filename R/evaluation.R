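# Tool-versus-physician comparison statistics: contingency tables, percent
# agreement, Cohen's kappa (with a null-hypothesis SE and one-sided test),
# diagnostic accuracy, triage dichotomization and under-triage, and exact
# reconstruction of integer 2x2 tables from published rounded summaries.

#' Cross-tabulate paired labels
#'
#' Builds the k-by-k contingency table of tool labels (rows) against
#' physician labels (columns) over a fixed, ordered category list.
#'
#' @param tool,physician equal-length vectors of labels.
#' @param categories ordered character vector of the legal categories; both
#'   label vectors must take values in it.
#' @return An integer matrix of class `contingency_table` with `dimnames`
#'   `list(tool = categories, physician = categories)`.
#' @export
#' @examples
#' tabulate_labels(c("A", "B", "B"), c("A", "B", "C"), c("A", "B", "C"))
tabulate_labels <- function(tool, physician, categories) {
  if (length(tool) != length(physician)) {
    stop("tool and physician label vectors must have equal length")
  }
  bad <- setdiff(unique(c(tool, physician)), categories)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  tab <- table(factor(tool, levels = categories),
               factor(physician, levels = categories))
  out <- matrix(as.integer(tab), nrow = length(categories),
                dimnames = list(tool = categories, physician = categories))
  class(out) <- c("contingency_table", class(out))
  out
}

as_contingency <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (any(x < 0)) stop("contingency counts must be non-negative")
  if (is.null(dimnames(x))) {
    dimnames(x) <- list(seq_len(nrow(x)), seq_len(ncol(x)))
  }
  names(dimnames(x)) <- c("tool", "physician")
  x
}

#' Observed percent agreement
#'
#' @param tab a square contingency table (tool rows, physician columns).
#' @return The proportion of pairs on the diagonal, in \[0, 1\].
#' @export
percent_agreement <- function(tab) {
  tab <- as_contingency(tab)
  if (nrow(tab) != ncol(tab)) stop("agreement needs a square table")
  n <- sum(tab)
  if (n == 0L) return(NA_real_)
  sum(diag(tab)) / n
}

#' Cohen's kappa with null-hypothesis test
#'
#' Chance-corrected agreement for a square contingency table:
#' `kappa = (po - pe) / (1 - pe)` with `po` the observed agreement and `pe`
#' the expected agreement from the row/column marginal products. The
#' standard error under the null hypothesis `kappa = 0` uses the Fleiss
#' marginal formula, and the p-value is one-sided for `kappa > 0`
#' (`z = kappa / se0`), which is the convention of standard statistical
#' software for the kappa test.
#'
#' @param tab a square contingency table (tool rows, physician columns).
#' @return A list of class `agreement_stats`: `n`, `po`, `pe`, `kappa`,
#'   `se0`, `z`, `p_value` and `landis_koch`. Degenerate marginals
#'   (`pe == 1`) give `NA` kappa.
#' @export
#' @examples
#' tab <- matrix(c(42, 6, 0, 121, 47, 7, 8, 2, 4), nrow = 3,
#'               dimnames = list(tool = c("A","B","C"), physician = c("A","B","C")))
#' cohens_kappa(tab)
cohens_kappa <- function(tab) {
  tab <- as_contingency(tab)
  if (nrow(tab) != ncol(tab)) stop("kappa needs a square table")
  n <- sum(tab)
  if (n == 0L) stop("kappa needs a non-empty table")
  po <- sum(diag(tab)) / n
  p_row <- rowSums(tab) / n
  p_col <- colSums(tab) / n
  pe <- sum(p_row * p_col)
  if (1 - pe < .Machine$double.eps^0.5) {
    kappa <- NA_real_
    se0 <- NA_real_
  } else {
    kappa <- (po - pe) / (1 - pe)
    se0 <- sqrt((pe + pe^2 - sum(p_row * p_col * (p_row + p_col))) /
                  (n * (1 - pe)^2))
  }
  z <- kappa / se0
  structure(
    list(n = n, po = po, pe = pe, kappa = kappa, se0 = se0, z = z,
         p_value = stats::pnorm(z, lower.tail = FALSE),
         landis_koch = landis_koch_band(kappa)),
    class = "agreement_stats"
  )
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "<agreement_stats> n = %d\n  agreement %.1f%% | kappa %.2f (%s) | z = %.2f, one-sided p = %.3g\n",
    x$n, 100 * x$po, x$kappa, x$landis_koch, x$z, x$p_value))
  invisible(x)
}

#' Diagnostic accuracy of a 2x2 confusion table
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' value, prevalence and observed agreement from the four cells of a
#' tool-versus-gold-standard table. Any statistic whose denominator is zero
#' is `NA` (never silently 0): a condition the gold standard never
#' identified has no defined sensitivity.
#'
#' @param tp,fn,fp,tn non-negative integer cell counts: true positive,
#'   false negative, false positive, true negative (tool versus gold
#'   standard).
#' @return A list of class `diagnostic_metrics` with the four counts, `n`,
#'   and proportions `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `prevalence`, `agreement`.
#' @export
#' @examples
#' binary_metrics(tp = 151, fn = 16, fp = 23, tn = 47) # fever detection
binary_metrics <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  n <- tp + fn + fp + tn
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(
    list(tp = tp, fn = fn, fp = fp, tn = tn, n = n,
         sensitivity = frac(tp, tp + fn),
         specificity = frac(tn, tn + fp),
         ppv = frac(tp, tp + fp),
         npv = frac(tn, tn + fn),
         prevalence = frac(tp + fn, n),
         agreement = frac(tp + tn, n)),
    class = "diagnostic_metrics"
  )
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "n/a" else sprintf("%.1f%%", 100 * v)
  cat("<diagnostic_metrics> n =", x$n, "\n")
  cat(sprintf("  tp %d  fn %d  fp %d  tn %d\n", x$tp, x$fn, x$fp, x$tn))
  cat("  sensitivity", pct(x$sensitivity), "| specificity", pct(x$specificity),
      "| PPV", pct(x$ppv), "| NPV", pct(x$npv), "\n")
  cat("  prevalence", pct(x$prevalence), "| agreement", pct(x$agreement), "\n")
  invisible(x)
}

#' Convert a 2x2 confusion table to a contingency table
#'
#' @inheritParams binary_metrics
#' @return A 2x2 `contingency_table` with categories `yes`/`no` (tool rows,
#'   gold-standard columns), suitable for [cohens_kappa()].
#' @export
confusion_table <- function(tp, fn, fp, tn) {
  out <- matrix(as.integer(c(tp, fn, fp, tn)), nrow = 2, byrow = TRUE,
                dimnames = list(tool = c("yes", "no"),
                                physician = c("yes", "no")))
  class(out) <- c("contingency_table", class(out))
  out
}

#' Reconstruct an integer 2x2 table from published rounded summaries
#'
#' Publications report diagnostic comparisons as rounded percentages
#' (prevalence, sensitivity, specificity, sometimes agreement/PPV/NPV)
#' rather than raw cell counts. This searches all integer 2x2 tables with
#' total `n` for the cell assignment whose implied summary proportions,
#' rounded half-up to the printed precision, reproduce the inputs.
#'
#' Exactly-matching tables are preferred; because published tables are
#' occasionally internally inconsistent by one unit in the last printed
#' digit, candidates within one such unit (one "ulp") of every input are
#' admitted as a fallback and ranked by (1) how many inputs they reproduce
#' exactly and (2) total absolute deviation. Remaining ties are broken by
#' the table whose implied agreement matches a supplied printed agreement;
#' if no candidate survives, an inconsistency error is raised rather than a
#' guess returned.
#'
#' @param n total number of pairs.
#' @param prevalence,sensitivity,specificity printed percentages (e.g.
#'   `70.5` for 70.5\%). `specificity` may be `NA` only when the implied
#'   negative count is zero.
#' @param agreement,ppv,npv optional printed percentages used for
#'   disambiguation and consistency checking.
#' @param digits printed decimal precision (default 1).
#' @return A list of class `reconstructed_confusion`: cells `tp`, `fn`,
#'   `fp`, `tn`, the [binary_metrics()] `metrics`, a logical `exact`
#'   (all inputs reproduced exactly after rounding) and a data frame
#'   `deviations` of per-statistic implied-versus-printed differences.
#' @export
#' @examples
#' # fever detection: n = 237, prevalence 70.5%, sensitivity 90.4%,
#' # specificity 67.1%  ->  unique table (151, 16, 23, 47)
#' reconstruct_confusion(237, 70.5, 90.4, 67.1, agreement = 83.5)
reconstruct_confusion <- function(n, prevalence, sensitivity, specificity,
                                  agreement = NULL, ppv = NULL, npv = NULL,
                                  digits = 1) {
  stopifnot(n > 0, n == round(n))
  n <- as.integer(n)
  ulp <- 10^(-digits)
  printed <- c(prevalence = prevalence, sensitivity = sensitivity,
               specificity = specificity,
               agreement = agreement %||% NA_real_,
               ppv = ppv %||% NA_real_, npv = npv %||% NA_real_)

  # candidate positives: every pos whose implied prevalence is within 1 ulp
  pos <- 0:n
  dev_prev <- abs(as_pct(pos / n, digits) - prevalence)
  pos <- pos[dev_prev <= ulp + 1e-9]
  cand <- list()
  for (p in pos) {
    neg <- n - p
    tp <- 0:p
    tp <- tp[if (p == 0) TRUE else
      abs(as_pct(tp / p, digits) - sensitivity) <= ulp + 1e-9]
    if (neg == 0) {
      tn <- 0L
      if (!is.na(specificity)) next  # spec printed but undefined
    } else {
      if (is.na(specificity)) {
        stop("specificity may be NA only when the implied negative count is 0")
      }
      tn <- 0:neg
      tn <- tn[abs(as_pct(tn / neg, digits) - specificity) <= ulp + 1e-9]
    }
    for (tpi in tp) for (tni in tn) {
      cand[[length(cand) + 1L]] <- c(tp = tpi, fn = p - tpi,
                                     fp = neg - tni, tn = tni)
    }
  }
  if (!length(cand)) {
    stop("inconsistency error: no integer 2x2 table with n = ", n,
         " reproduces the printed proportions within one printed unit")
  }

  score <- function(cells) {
    m <- binary_metrics(cells[["tp"]], cells[["fn"]], cells[["fp"]], cells[["tn"]])
    implied <- c(prevalence = m$prevalence, sensitivity = m$sensitivity,
                 specificity = m$specificity, agreement = m$agreement,
                 ppv = m$ppv, npv = m$npv)
    use <- !is.na(printed)
    dev <- as_pct(implied[use], digits) - printed[use]
    dev[is.na(dev)] <- Inf  # printed value for an undefined statistic
    list(metrics = m, dev = dev,
         n_exact = sum(abs(dev) < 1e-9), total_dev = sum(abs(dev)))
  }
  scored <- lapply(cand, score)
  ok <- vapply(scored, function(s) all(abs(s$dev) <= ulp + 1e-9), logical(1))
  if (!any(ok)) {
    stop("inconsistency error: printed proportions disagree by more than one ",
         "printed unit; no credible integer table exists")
  }
  cand <- cand[ok]; scored <- scored[ok]
  rank <- order(-vapply(scored, `[[`, numeric(1), "n_exact"),
                vapply(scored, `[[`, numeric(1), "total_dev"))
  best <- rank[[1]]
  tied <- rank[vapply(scored[rank], function(s)
    s$n_exact == scored[[best]]$n_exact &&
      abs(s$total_dev - scored[[best]]$total_dev) < 1e-9, logical(1))]
  if (length(tied) > 1L) {
    if (!is.na(printed[["agreement"]])) {
      agree_dev <- vapply(scored[tied], function(s) abs(s$dev[["agreement"]]),
                          numeric(1))
      tied <- tied[agree_dev == min(agree_dev)]
    }
    if (length(tied) > 1L) {
      stop("inconsistency error: ", length(tied), " integer tables match the ",
           "printed proportions equally well; supply `agreement` (or ppv/npv) ",
           "to disambiguate")
    }
  }
  cells <- cand[[tied[[1]]]]
  sc <- scored[[tied[[1]]]]
  structure(
    list(tp = as.integer(cells[["tp"]]), fn = as.integer(cells[["fn"]]),
         fp = as.integer(cells[["fp"]]), tn = as.integer(cells[["tn"]]),
         metrics = sc$metrics,
         exact = all(abs(sc$dev) < 1e-9),
         deviations = data.frame(statistic = names(sc$dev),
                                 deviation = unname(sc$dev))),
    class = "reconstructed_confusion"
  )
}

#' @export
print.reconstructed_confusion <- function(x, ...) {
  cat(sprintf("<reconstructed_confusion> tp %d  fn %d  fp %d  tn %d (%s)\n",
              x$tp, x$fn, x$fp, x$tn,
              if (x$exact) "exact match" else "within one printed unit"))
  invisible(x)
}

#' Dichotomize a 3x3 triage table to hospital versus home
#'
#' Collapses the A/B/C triage cross-tabulation to the clinically decisive
#' 2x2 question: should the child be presented at a hospital (levels A or
#' B) or cared for at home (level C)?
#'
#' @param tab a 3x3 contingency table with categories A, B, C (tool rows,
#'   physician columns).
#' @return A 2x2 `contingency_table` with categories `hospital`, `home`.
#' @export
dichotomize_triage <- function(tab) {
  tab <- as_contingency(tab)
  if (!identical(rownames(tab), c("A", "B", "C")) ||
      !identical(colnames(tab), c("A", "B", "C"))) {
    stop("expected a 3x3 table with categories A, B, C")
  }
  grp <- c(A = "hospital", B = "hospital", C = "home")
  out <- matrix(0L, 2, 2,
                dimnames = list(tool = c("hospital", "home"),
                                physician = c("hospital", "home")))
  for (i in rownames(tab)) for (j in colnames(tab)) {
    out[grp[[i]], grp[[j]]] <- out[grp[[i]], grp[[j]]] + tab[i, j]
  }
  class(out) <- c("contingency_table", class(out))
  out
}

#' Under-triage rate
#'
#' The proportion of all cases the tool ranked as home care (C) although
#' the physician required clinical care (A or B) — the clinically dangerous
#' error direction.
#'
#' @inheritParams dichotomize_triage
#' @return Proportion in \[0, 1\].
#' @export
undertriage_rate <- function(tab) {
  tab <- as_contingency(tab)
  if (!identical(rownames(tab), c("A", "B", "C")) ||
      !identical(colnames(tab), c("A", "B", "C"))) {
    stop("expected a 3x3 table with categories A, B, C")
  }
  (tab["C", "A"] + tab["C", "B"]) / sum(tab)
}

#' Physician-level capture rate
#'
#' Of the cases the physician assigned to `level`, the proportion the tool
#' assigned to the same level — e.g. how many physician-confirmed
#' emergencies (A) the tool also flagged as emergencies.
#'
#' @inheritParams dichotomize_triage
#' @param level the triage level of interest (default `"A"`).
#' @return Proportion in \[0, 1\] (`NA` if the physician never used the
#'   level).
#' @export
capture_rate <- function(tab, level = "A") {
  tab <- as_contingency(tab)
  if (!level %in% colnames(tab)) stop("unknown level: ", level)
  denom <- sum(tab[, level])
  if (denom == 0L) return(NA_real_)
  tab[level, level] / denom
}
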