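# Published diagnostic panel for the NEWS2-L (48-h mortality, prehospital
# advanced life support, ICU admission): group sizes, printed cut-offs,
# sensitivity/specificity, and the derived metrics at printed rounding.
# These printed constants are inputs to reproduce_table3().
published_panel <- function() {
  list(
    death_48h = list(n_pos = 21, n_neg = 340, cutoff = 9.5,
                     se = 0.952, sp = 0.812,
                     printed = c(PPV = 23.8, NPV = 99.6, LR_pos = 5.06,
                                 LR_neg = 0.06, OR = 86.25, DA = 82.0)),
    pals = list(n_pos = 51, n_neg = 310, cutoff = 6.9,
                se = 0.922, sp = 0.616,
                printed = c(PPV = 28.3, NPV = 97.9, LR_pos = 2.40,
                            LR_neg = 0.13, OR = 18.26, DA = 65.9)),
    icu = list(n_pos = 31, n_neg = 330, cutoff = 10.3,
               se = 0.613, sp = 0.855,
               printed = c(PPV = 28.4, NPV = 95.9, LR_pos = 4.21,
                           LR_neg = 0.45, OR = 9.30, DA = 83.4))
  )
}

# display rounding used by the published panel: percentages to one decimal,
# ratios to two
round_for_display <- function(metric, value) {
  if (metric %in% c("LR_pos", "LR_neg", "OR")) {
    round_half_up(value, 2)
  } else {
    round_half_up(100 * value, 1)
  }
}

#' Reproduce the published NEWS2-L diagnostic panel from printed constants
#'
#' Self-contained reconstruction of the published cut-off metric panel: for
#' each outcome the 2x2 counts are rebuilt from the group sizes and the
#' printed sensitivity/specificity via [reconstruct_contingency()], the
#' derived metrics (PPV, NPV, LR+, LR-, OR, DA) are recomputed with
#' [compute_metrics()], and each is compared with the printed value at its
#' printed precision.
#'
#' One printed value is internally inconsistent: the advanced-life-support
#' odds ratio is printed as 18.26, while the counts implied by the printed
#' prevalence/Se/Sp (tp 47, fp 119, fn 4, tn 191) give 18.86.  Every other
#' metric in that column matches those counts; the mismatch is reported as
#' such, not forced.
#'
#' @return A `data.frame` with columns `outcome`, `metric`, `printed`,
#'   `recomputed` (at printed rounding), `recomputed_exact`, `match`.
#' @examples
#' tab <- reproduce_table3()
#' subset(tab, !match)  # the single documented discrepancy
#' @export
reproduce_table3 <- function() {
  panel <- published_panel()
  rows <- list()
  for (outcome in names(panel)) {
    p <- panel[[outcome]]
    ct <- reconstruct_contingency(p$n_pos, p$n_neg, p$se, p$sp)
    rep <- compute_metrics(ct, cutoff = p$cutoff)
    for (metric in names(p$printed)) {
      exact <- rep$estimate[rep$metric == metric]
      disp <- round_for_display(metric, exact)
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = outcome, metric = metric,
        printed = p$printed[[metric]],
        recomputed = disp, recomputed_exact = exact,
        match = isTRUE(all.equal(disp, p$printed[[metric]],
                                 tolerance = 1e-9)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full score -> ROC -> cut-off -> metrics analysis
#'
#' For every requested (outcome, score) pair: builds the empirical ROC
#' curve, the DeLong AUC confidence interval, the Youden-optimal cut-off,
#' and the diagnostic metric panel at that cut-off; then runs pairwise
#' paired DeLong comparisons among the requested scores for each outcome.
#' Rows with incomplete vitals are excluded (with a message); an outcome
#' with a single class is skipped with a warning and the run continues.
#'
#' @param cohort A cohort `data.frame` (scored or raw; it is passed through
#'   [score_cohort()] if score columns are absent).
#' @param outcomes Subset of `c("death_48h", "pals", "icu")`.
#' @param scores Subset of `c("news2", "news2_l", "lactate")`.
#' @param ci_level Confidence level for all intervals.
#' @return An object of class `"syncope_analysis"`: a list with one element
#'   per analysed outcome, each containing per-score results (`roc`,
#'   `auc_ci`, `youden`, `metrics`) and `comparisons` (pairwise DeLong
#'   tests); plus attributes `n_used` and `n_excluded`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 400, seed = 7))
#' fit <- run_full_analysis(cohort, outcomes = "death_48h")
#' summary(fit)
#' @export
run_full_analysis <- function(cohort,
                              outcomes = c("death_48h", "pals", "icu"),
                              scores = c("news2", "news2_l", "lactate"),
                              ci_level = 0.95) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  scores <- match.arg(scores, several.ok = TRUE)
  if (!all(c("news2", "news2_l") %in% names(cohort))) {
    cohort <- score_cohort(cohort)
  }
  usable <- !is.na(cohort$news2_l)
  n_excl <- sum(!usable)
  cohort <- cohort[usable, ]

  result <- list()
  for (outcome in outcomes) {
    labels <- cohort[[outcome]]
    if (length(unique(labels)) < 2L) {
      warning("outcome '", outcome,
              "' has a single class in this cohort; skipped")
      next
    }
    per_score <- list()
    for (sc in scores) {
      x <- cohort[[sc]]
      roc <- roc_curve(x, labels)
      yj <- youden_cutoff(x, labels)
      ct <- build_contingency(x, labels, yj$cutoff)
      per_score[[sc]] <- list(
        roc = roc,
        auc_ci = auc_ci_delong(x, labels, ci_level),
        youden = yj,
        metrics = compute_metrics(ct, ci_level, cutoff = yj$cutoff))
    }
    comparisons <- list()
    if (length(scores) > 1L) {
      pairs <- utils::combn(scores, 2, simplify = FALSE)
      for (pr in pairs) {
        comparisons[[paste(pr, collapse = "_vs_")]] <-
          compare_auc_delong(cohort[[pr[1]]], cohort[[pr[2]]], labels,
                             ci_level)
      }
    }
    result[[outcome]] <- list(scores = per_score, comparisons = comparisons)
  }
  structure(result, n_used = nrow(cohort), n_excluded = n_excl,
            ci_level = ci_level, class = "syncope_analysis")
}

#' @export
summary.syncope_analysis <- function(object, ...) {
  rows <- list()
  for (outcome in names(object)) {
    for (sc in names(object[[outcome]]$scores)) {
      r <- object[[outcome]]$scores[[sc]]
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = outcome, score = sc,
        auc = r$roc$auc,
        auc_low = r$auc_ci$ci[1], auc_high = r$auc_ci$ci[2],
        cutoff = r$youden$cutoff,
        sensitivity = r$youden$sensitivity,
        specificity = r$youden$specificity)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.syncope_analysis <- function(x, ...) {
  cat("Syncope risk-score analysis (n = ", attr(x, "n_used"),
      if (attr(x, "n_excluded") > 0) {
        paste0(", ", attr(x, "n_excluded"), " excluded")
      },
      ")\n\n", sep = "")
  print(summary(x), row.names = FALSE)
  for (outcome in names(x)) {
    if (length(x[[outcome]]$comparisons)) {
      cat("\nPaired AUC comparisons for", outcome, ":\n")
      for (nm in names(x[[outcome]]$comparisons)) {
        cmp <- x[[outcome]]$comparisons[[nm]]
        cat(sprintf("  %-22s diff = %+.4f, p = %.4f\n", nm,
                    cmp$difference, cmp$p_value))
      }
    }
  }
  invisible(x)
}
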