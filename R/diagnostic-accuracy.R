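#' Construct a 2x2 diagnostic contingency table
#'
#' @param tp,fp,fn,tn Non-negative integer counts (true/false
#'   positives/negatives against the reference outcome).
#' @return An object of class `"contingency_table"`: a list with the four
#'   counts plus `n`, `n_pos` (diseased) and `n_neg` (non-diseased).
#' @export
contingency_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("tp, fp, fn, tn must be non-negative integers")
  }
  if (sum(counts) == 0) stop("contingency table must contain at least one case")
  structure(
    list(tp = as.integer(tp), fp = as.integer(fp),
         fn = as.integer(fn), tn = as.integer(tn),
         n = as.integer(sum(counts)),
         n_pos = as.integer(tp + fn), n_neg = as.integer(fp + tn)),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("test +", "test -"),
                              c("outcome +", "outcome -")))
  print(m)
  invisible(x)
}

#' Classify scores at a cut-off into a 2x2 table
#'
#' Test-positive is `score >= cutoff` (ties count as positive; the pipeline
#' reports cut-offs as midpoints between achievable score values, so ties
#' arise only in synthetic edge cases).
#'
#' @param scores Numeric vector of test scores (higher = more severe).
#' @param labels Binary outcome vector (0/1 or logical), aligned to `scores`.
#' @param cutoff Numeric decision threshold.
#' @return A [contingency_table()].
#' @examples
#' build_contingency(c(10, 8, 12, 3), c(1, 0, 1, 0), 9.5)
#' @export
build_contingency <- function(scores, labels, cutoff) {
  labels <- check_binary_labels(scores, labels)
  pos <- scores >= cutoff
  contingency_table(tp = sum(pos & labels == 1),
                    fp = sum(pos & labels == 0),
                    fn = sum(!pos & labels == 1),
                    tn = sum(!pos & labels == 0))
}

# shared validation for score/label pairs; returns labels as 0/1 integer
check_binary_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have the same length")
  }
  if (anyNA(scores) || anyNA(labels)) stop("scores and labels must be complete")
  labels <- as.integer(as.logical(labels) | labels == 1)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  if (length(unique(labels)) < 2L) {
    stop("labels contain a single class; both outcomes are required")
  }
  labels
}

#' Reconstruct a 2x2 table from group sizes and printed Se/Sp
#'
#' Inverts a published sensitivity/specificity pair back to integer counts
#' using the reported group sizes, with half-up rounding:
#' `tp = round(se * n_pos)`, `tn = round(sp * n_neg)`.  This is how the
#' package rebuilds a published diagnostic panel when the patient-level data
#' are not deposited.
#'
#' @param n_pos,n_neg Positive (outcome present) and negative group sizes.
#' @param se,sp Sensitivity and specificity as fractions in \[0, 1\].
#' @return A [contingency_table()].
#' @examples
#' reconstruct_contingency(21, 340, 0.952, 0.812)
#' @export
reconstruct_contingency <- function(n_pos, n_neg, se, sp) {
  stopifnot(n_pos > 0, n_neg > 0, se >= 0, se <= 1, sp >= 0, sp <= 1)
  tp <- round_half_up(se * n_pos)
  tn <- round_half_up(sp * n_neg)
  contingency_table(tp = tp, fp = n_neg - tn, fn = n_pos - tp, tn = tn)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
ci_wilson <- function(k, n, level = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n, level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(low = max(0, centre - half), high = min(1, centre + half))
}

# log-scale interval for a likelihood ratio (Simel et al. construction):
# var(log LR) from the two binomial proportions it is a ratio of.
ci_log_ratio <- function(point, var_log, level) {
  if (!is.finite(point) || point <= 0 || !is.finite(var_log)) {
    return(c(low = NA_real_, high = NA_real_))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(low = exp(log(point) - z * sqrt(var_log)),
    high = exp(log(point) + z * sqrt(var_log)))
}

#' Full diagnostic-accuracy panel from a 2x2 table
#'
#' Computes prevalence, sensitivity (Se), specificity (Sp), positive and
#' negative predictive values (PPV/NPV), positive and negative likelihood
#' ratios (LR+ = Se/(1-Sp), LR- = (1-Se)/Sp), the diagnostic odds ratio
#' (OR = tp*tn / (fp*fn)) and diagnostic accuracy (DA = (tp+tn)/n), each
#' with a confidence interval: Wilson score intervals for the proportions,
#' log-normal intervals for the likelihood ratios, and a Woolf log interval
#' for the odds ratio.  When the table has an empty cell the odds ratio
#' (only) uses the Haldane-Anscombe +0.5 correction and the report carries a
#' `zero_cell` flag.
#'
#' @param ct A [contingency_table()].
#' @param ci_level Confidence level for all intervals (default 0.95).
#' @param cutoff Optional cut-off the table was built at, carried for
#'   reporting.
#' @return A `data.frame` of class `"diagnostic_report"` with columns
#'   `metric`, `estimate`, `ci_low`, `ci_high`; attributes `contingency`,
#'   `ci_level`, `cutoff` and `zero_cell`.
#' @examples
#' compute_metrics(reconstruct_contingency(21, 340, 0.952, 0.812))
#' @export
compute_metrics <- function(ct, ci_level = 0.95, cutoff = NA_real_) {
  stopifnot(inherits(ct, "contingency_table"),
            ci_level > 0, ci_level < 1)
  tp <- ct$tp; fp <- ct$fp; fn <- ct$fn; tn <- ct$tn; n <- ct$n
  npos <- ct$n_pos; nneg <- ct$n_neg

  prop <- function(name, k, m) {
    ci <- if (m > 0) ci_wilson(k, m, ci_level) else c(NA_real_, NA_real_)
    data.frame(metric = name, estimate = if (m > 0) k / m else NA_real_,
               ci_low = ci[[1]], ci_high = ci[[2]])
  }

  se <- tp / npos
  sp <- tn / nneg
  lr_pos <- se / (1 - sp)
  lr_neg <- (1 - se) / sp
  # var(log LR) = 1/a - 1/(a+c) + 1/b - 1/(b+d) for the ratio of the two
  # involved proportions; infinite/undefined with the relevant zero cells
  v_lrp <- 1 / tp - 1 / npos + 1 / fp - 1 / nneg
  v_lrn <- 1 / fn - 1 / npos + 1 / tn - 1 / nneg

  zero_cell <- any(c(tp, fp, fn, tn) == 0L)
  if (zero_cell) {
    or_pt <- ((tp + 0.5) * (tn + 0.5)) / ((fp + 0.5) * (fn + 0.5))
    v_or <- 1 / (tp + 0.5) + 1 / (fp + 0.5) + 1 / (fn + 0.5) + 1 / (tn + 0.5)
  } else {
    or_pt <- (tp * tn) / (fp * fn)
    v_or <- 1 / tp + 1 / fp + 1 / fn + 1 / tn
  }

  lr_row <- function(name, point, var_log) {
    ci <- ci_log_ratio(point, var_log, ci_level)
    data.frame(metric = name, estimate = point,
               ci_low = ci[[1]], ci_high = ci[[2]])
  }

  out <- rbind(
    prop("prevalence", npos, n),
    prop("Se", tp, npos),
    prop("Sp", tn, nneg),
    prop("PPV", tp, tp + fp),
    prop("NPV", tn, tn + fn),
    lr_row("LR_pos", lr_pos, v_lrp),
    lr_row("LR_neg", lr_neg, v_lrn),
    lr_row("OR", or_pt, v_or),
    prop("DA", tp + tn, n)
  )
  rownames(out) <- NULL
  structure(out,
            contingency = ct, ci_level = ci_level, cutoff = cutoff,
            zero_cell = zero_cell,
            class = c("diagnostic_report", "data.frame"))
}

#' @rdname compute_metrics
#' @export
diagnostic_metrics <- compute_metrics

#' @export
print.diagnostic_report <- function(x, digits = 3, ...) {
  ct <- attr(x, "contingency")
  cat("Diagnostic accuracy (n = ", ct$n, ", ", ct$n_pos, " outcome-positive",
      if (!is.na(attr(x, "cutoff"))) paste0(", cutoff = ", attr(x, "cutoff")),
      ")\n", sep = "")
  if (isTRUE(attr(x, "zero_cell"))) {
    cat("note: empty cell; odds ratio uses the +0.5 correction\n")
  }
  print.data.frame(cbind(x[1], round(x[-1], digits)), row.names = FALSE)
  invisible(x)
}

#' Sample size for estimating a proportion
#'
#' Normal-approximation sample size for estimating a proportion `p` to
#' within `margin` at confidence `conf`:
#' `n = ceil(z^2 p (1-p) / margin^2)`, optionally inflated by
#' `1 / (1 - loss)` for an anticipated loss-to-follow-up fraction.
#'
#' @param p Expected proportion (0 < p < 1).
#' @param margin Absolute margin of error, as a fraction.
#' @param conf Confidence level (default 0.95).
#' @param loss Anticipated loss fraction in \[0, 1).
#' @return A list with `n` (the estimation sample size) and `n_inflated`
#'   (after loss inflation; equal to `n` when `loss = 0`).
#' @examples
#' sample_size_proportion(0.0593, 0.025)        # 343 cases
#' sample_size_proportion(0.5, 0.05)            # textbook worst case: 385
#' @export
sample_size_proportion <- function(p, margin, conf = 0.95, loss = 0) {
  stopifnot(p > 0, p < 1, margin > 0, margin < 1,
            conf > 0, conf < 1, loss >= 0, loss < 1)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  n <- ceiling(z^2 * p * (1 - p) / margin^2)
  n_inflated <- if (loss > 0) ceiling(n / (1 - loss)) else n
  list(n = n, n_inflated = n_inflated)
}
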