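# Independent oracles used across test files.  These deliberately use the
# naive O(n^2) / exhaustive formulations so they share no code with the
# package implementations they check.

# AUC by explicit pair counting over all (positive, negative) pairs
auc_pair_counting <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Youden optimum by exhaustive scan over every candidate cut-off
youden_exhaustive <- function(scores, labels) {
  v <- sort(unique(scores))
  cand <- c(v[1] - 0.5,
            if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
            v[length(v)] + 0.5)
  best <- NULL
  for (cutoff in cand) {
    se <- mean(scores[labels == 1] >= cutoff)
    sp <- mean(scores[labels == 0] < cutoff)
    j <- se + sp - 1
    if (is.null(best) || j > best$j + 1e-12) {
      best <- list(cutoff = cutoff, j = j)
    }
  }
  best
}

# random score/label instance guaranteed to contain both classes
random_instance <- function(n, tie_prone = FALSE) {
  labels <- integer(n)
  while (length(unique(labels)) < 2) labels <- rbinom(n, 1, 0.4)
  scores <- if (tie_prone) {
    sample(0:9, n, replace = TRUE) + labels * sample(0:3, n, replace = TRUE)
  } else {
    rnorm(n) + labels
  }
  list(scores = scores, labels = labels)
}

# a small complete cohort data frame for scoring tests
toy_cohort <- function() {
  data.frame(
    patient_id = c("a", "b", "c"),
    age = c(70, 80, 60), sex = c("female", "male", "female"),
    rr = c(16, 22, 8), spo2 = c(96, 93, 83),
    on_oxygen = c(FALSE, FALSE, TRUE),
    spo2_scale = c("scale1", "scale1", "scale2"),
    temp_c = c(36.5, 35.7, 34.9), sbp = c(127, 105, 90),
    hr = c(71, 82, 40), gcs = c(15, 14, 3),
    lactate = c(1.2, 2.6, 5.2),
    death_48h = c(0, 0, 1), pals = c(0, 0, 1), icu = c(0, 0, 1),
    admitted = c(0, 1, 1),
    ecg_rhythm = c("sinus", "sinus", "av_block"))
}

# silence the expected incomplete-row messages and out-of-device-range
# lactate warnings when they are not what a test is about
quietly <- function(expr) suppressWarnings(suppressMessages(expr))
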