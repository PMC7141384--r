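#' Empirical ROC curve
#'
#' Builds the empirical ROC curve for a continuous (or ordinal) score
#' against a binary outcome, with the convention that higher scores indicate
#' greater severity.  Candidate thresholds are the midpoints between
#' adjacent distinct observed score values (plus the two infinite
#' thresholds); tied scores are grouped at a single operating point.  The
#' AUC is the trapezoidal area, which on the empirical curve equals the
#' Mann-Whitney pair-counting estimate exactly.
#'
#' @param scores Numeric score vector.
#' @param labels Binary outcome vector aligned to `scores`; both classes
#'   must be present.
#' @return An object of class `"roc_curve"`: a list with `thresholds`
#'   (descending, from `Inf` to `-Inf`), `fpr`, `tpr` (the operating points,
#'   from (0,0) to (1,1)), `auc`, `n_pos`, `n_neg`.
#' @examples
#' roc_curve(c(1, 2, 2, 3), c(0, 0, 1, 1))$auc  # 0.875
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_binary_labels(scores, labels)
  v <- sort(unique(scores), decreasing = TRUE)
  thr <- c(Inf, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2, -Inf)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  tpr <- vapply(thr, function(t) sum(pos >= t), numeric(1)) / n_pos
  fpr <- vapply(thr, function(t) sum(neg >= t), numeric(1)) / n_neg
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve: ", x$n_pos, " positives / ", x$n_neg, " negatives, ",
      length(x$thresholds), " operating points\nAUC = ",
      format(x$auc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Mann-Whitney (rank) estimate of the AUC
#'
#' The probability that a randomly chosen positive outranks a randomly
#' chosen negative, with ties counting one half.  Computed via midranks in
#' O(n log n); identical (to machine precision) to the trapezoidal area of
#' the empirical ROC curve.
#'
#' @inheritParams roc_curve
#' @return The AUC as a single number in \[0, 1\].
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- check_binary_labels(scores, labels)
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  r <- rank(c(pos, neg), ties.method = "average")
  m <- length(pos)
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * length(neg))
}

# DeLong structural components.  v10[i] = placement of positive i among the
# negatives (P(pos_i > neg) + 0.5 P(tie)); v01[j] symmetric.  mean(v10) =
# mean(v01) = AUC.  Midrank formulation keeps this O(n log n).
delong_components <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  m <- length(pos)
  n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(pos, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(neg, ties.method = "average")) / m
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' DeLong confidence interval for an AUC
#'
#' Normal-approximation interval based on the DeLong structural-component
#' variance, truncated to \[0, 1\].  With perfect separation the component
#' variance is zero and the interval collapses to the point estimate; the
#' result then carries `degenerate = TRUE`.
#'
#' @inheritParams roc_curve
#' @param ci_level Confidence level (default 0.95).
#' @return A list with `auc`, `ci` (length-2 vector), `se` (standard error
#'   of the AUC) and `degenerate`.
#' @export
auc_ci_delong <- function(scores, labels, ci_level = 0.95) {
  labels <- check_binary_labels(scores, labels)
  dc <- delong_components(scores, labels)
  if (dc$m < 2L || dc$n < 2L) {
    stop("at least two positives and two negatives are required")
  }
  v <- stats::var(dc$v10) / dc$m + stats::var(dc$v01) / dc$n
  if (v <= .Machine$double.eps) {
    return(list(auc = dc$auc, ci = c(dc$auc, dc$auc), se = 0,
                degenerate = TRUE))
  }
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  list(auc = dc$auc,
       ci = c(max(0, dc$auc - z * sqrt(v)), min(1, dc$auc + z * sqrt(v))),
       se = sqrt(v), degenerate = FALSE)
}

#' Paired DeLong test comparing two AUCs on the same patients
#'
#' Compares the AUCs of two scores measured on the same cohort (paired
#' design) using the covariance of their DeLong structural components; the
#' p-value is two-sided.  Identical rankings (including any strictly
#' increasing transform of one score into the other) give a zero difference
#' and p = 1.
#'
#' @param scores_a,scores_b Two score vectors aligned to the same `labels`.
#' @param labels Binary outcome vector.
#' @param ci_level Confidence level used for the difference interval.
#' @return An object of class `"auc_comparison"`: a list with `auc_a`,
#'   `auc_b`, `difference` (a minus b), `z`, `p_value`, `ci_difference`.
#' @examples
#' set.seed(7)
#' y <- rep(c(0, 1), each = 40)
#' a <- rnorm(80) + y
#' compare_auc_delong(a, a + 100, y)$p_value  # shift-invariant: 1
#' @export
compare_auc_delong <- function(scores_a, scores_b, labels, ci_level = 0.95) {
  if (length(scores_a) != length(scores_b)) {
    stop("scores_a and scores_b must be aligned to the same patients")
  }
  labels <- check_binary_labels(scores_a, labels)
  da <- delong_components(scores_a, labels)
  db <- delong_components(scores_b, labels)
  s10 <- stats::cov(cbind(da$v10, db$v10))
  s01 <- stats::cov(cbind(da$v01, db$v01))
  v_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / da$m +
            (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / da$n
  diff <- da$auc - db$auc
  if (v_diff <= .Machine$double.eps) {
    z <- 0
    p <- if (abs(diff) < 1e-12) 1 else 0
  } else {
    z <- diff / sqrt(v_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  zq <- stats::qnorm(1 - (1 - ci_level) / 2)
  half <- if (v_diff > 0) zq * sqrt(v_diff) else 0
  structure(list(auc_a = da$auc, auc_b = db$auc, difference = diff,
                 z = z, p_value = p,
                 ci_difference = c(diff - half, diff + half)),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat("Paired DeLong AUC comparison\n",
      "  AUC A = ", format(x$auc_a, digits = 4),
      ", AUC B = ", format(x$auc_b, digits = 4),
      ", difference = ", format(x$difference, digits = 4), "\n",
      "  z = ", format(x$z, digits = 4),
      ", two-sided p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Youden-index optimal cut-off
#'
#' Scans every candidate cut-off (midpoints between adjacent distinct
#' observed score values, plus one half-unit below the minimum and above the
#' maximum) and returns the one maximising Youden's J = Se + Sp - 1.  Ties
#' are broken toward the lower cut-off, i.e. toward higher sensitivity — in
#' a triage context missing a death is worse than over-triage.
#'
#' @inheritParams roc_curve
#' @return A list with `cutoff`, `sensitivity`, `specificity` and `j`.
#' @examples
#' youden_cutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))  # cutoff 2.5, Se = Sp = 1
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- check_binary_labels(scores, labels)
  v <- sort(unique(scores))
  cand <- c(v[1] - 0.5,
            if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
            v[length(v)] + 0.5)
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  se <- vapply(cand, function(cutoff) mean(pos >= cutoff), numeric(1))
  sp <- vapply(cand, function(cutoff) mean(neg < cutoff), numeric(1))
  j <- se + sp - 1
  best <- which(j >= max(j) - 1e-12)[1]  # first index = lowest cutoff
  list(cutoff = cand[best], sensitivity = se[best],
       specificity = sp[best], j = j[best])
}
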