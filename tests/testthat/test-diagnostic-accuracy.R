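test_that("scores are classified at a cut-off with ties test-positive", {
  ct <- build_contingency(c(10, 8, 12, 3), c(1, 0, 1, 0), 9.5)
  expect_identical(ct[c("tp", "fp", "fn", "tn")],
                   list(tp = 2L, fp = 0L, fn = 0L, tn = 2L))
  # tie at the cut-off counts as test-positive
  tie <- build_contingency(c(5, 5), c(1, 0), 5)
  expect_identical(tie[c("tp", "fp", "fn", "tn")],
                   list(tp = 1L, fp = 1L, fn = 0L, tn = 0L))
  # hand-enumerated: scores 1..10, outcome positive above 7, cut-off 5
  ten <- build_contingency(1:10, as.integer(1:10 > 7), 5)
  expect_identical(ten[c("tp", "fp", "fn", "tn")],
                   list(tp = 3L, fp = 3L, fn = 0L, tn = 4L))
  expect_error(build_contingency(1:4, c(1, 1, 1, 1), 2), "single class")
  expect_error(build_contingency(1:3, c(1, 0), 2), "same length")
})

test_that("printed Se/Sp invert to integer counts by half-up rounding", {
  mort <- reconstruct_contingency(21, 340, 0.952, 0.812)
  expect_identical(mort[c("tp", "fp", "fn", "tn")],
                   list(tp = 20L, fp = 64L, fn = 1L, tn = 276L))
  icu <- reconstruct_contingency(31, 330, 0.613, 0.855)
  expect_identical(icu[c("tp", "fp", "fn", "tn")],
                   list(tp = 19L, fp = 48L, fn = 12L, tn = 282L))
  perfect <- reconstruct_contingency(10, 10, 1, 1)
  expect_identical(perfect[c("tp", "fp", "fn", "tn")],
                   list(tp = 10L, fp = 0L, fn = 0L, tn = 10L))
})

test_that("round-trip through reconstruction recovers Se and Sp", {
  # Se recovery depends only on (se, n_pos); likewise Sp on (sp, n_neg);
  # the half-up rounding bound is 0.5/n
  grid <- seq(0, 1, by = 0.001)
  for (n in c(10L, 21L, 100L, 340L)) {
    tp <- floor(grid * n + 0.5 + sqrt(.Machine$double.eps) * grid * n)
    expect_true(all(abs(tp / n - grid) <= 0.5 / n + 1e-12),
                label = sprintf("round-trip bound at n = %d", n))
    # the package path agrees with the direct arithmetic on a subsample
    for (se in grid[seq(1, length(grid), by = 97)]) {
      ct <- reconstruct_contingency(n, n, se, 0.5)
      expect_lte(abs(ct$tp / n - se), 0.5 / n + 1e-12)
    }
  }
})

test_that("the metric panel is internally consistent with its counts", {
  ct <- contingency_table(tp = 20, fp = 64, fn = 1, tn = 276)
  rep <- compute_metrics(ct)
  g <- function(m) rep$estimate[rep$metric == m]
  expect_equal(g("Se"), 20 / 21, tolerance = 1e-12)
  expect_equal(g("Sp"), 276 / 340, tolerance = 1e-12)
  expect_equal(g("LR_pos"), g("Se") / (1 - g("Sp")), tolerance = 1e-12)
  expect_equal(g("LR_neg"), (1 - g("Se")) / g("Sp"), tolerance = 1e-12)
  expect_equal(g("OR"), (20 * 276) / (64 * 1), tolerance = 1e-12)
  expect_equal(g("DA"), 296 / 361, tolerance = 1e-12)
  expect_equal(g("prevalence"), 21 / 361, tolerance = 1e-12)
  # Bayes consistency: PPV from counts equals the prevalence-weighted form
  prev <- g("prevalence")
  expect_equal(g("PPV"),
               g("Se") * prev / (g("Se") * prev + (1 - g("Sp")) * (1 - prev)),
               tolerance = 1e-12)
  # OR as the Se/Sp cross-product when no cell is zero
  expect_equal(g("OR"),
               (g("Se") / (1 - g("Se"))) * (g("Sp") / (1 - g("Sp"))),
               tolerance = 1e-9)
  # interval ordering
  finite <- is.finite(rep$ci_low) & is.finite(rep$ci_high)
  expect_true(all(rep$ci_low[finite] <= rep$estimate[finite] + 1e-12))
  expect_true(all(rep$estimate[finite] <= rep$ci_high[finite] + 1e-12))
})

test_that("a perfect test is degenerate but finite under the correction", {
  rep <- compute_metrics(contingency_table(tp = 10, fp = 0, fn = 0, tn = 10))
  g <- function(m) rep$estimate[rep$metric == m]
  for (m in c("Se", "Sp", "PPV", "NPV", "DA")) expect_equal(g(m), 1)
  expect_equal(g("LR_neg"), 0)
  expect_true(attr(rep, "zero_cell"))
  expect_equal(g("OR"), (10.5 * 10.5) / (0.5 * 0.5))  # +0.5 correction
  expect_true(is.finite(g("OR")))
})

test_that("Wilson intervals achieve near-nominal coverage", {
  set.seed(20240510)
  for (p in c(0.05, 0.5, 0.95)) {
    k <- rbinom(10000, 50, p)
    covered <- vapply(k, function(ki) {
      ci <- ci_wilson(ki, 50)
      ci[1] <= p && p <= ci[2]
    }, logical(1))
    expect_gte(mean(covered), 0.93)
    expect_lte(mean(covered), 0.97)
  }
})

test_that("sample size for a proportion matches direct evaluation", {
  expect_identical(sample_size_proportion(0.0593, 0.025, 0.95)$n, 343)
  expect_identical(sample_size_proportion(0.5, 0.05, 0.95)$n, 385)
  # loss inflation is monotone and inactive at zero loss
  s0 <- sample_size_proportion(0.1, 0.03, 0.95, loss = 0)
  s15 <- sample_size_proportion(0.1, 0.03, 0.95, loss = 0.15)
  expect_identical(s0$n, s0$n_inflated)
  expect_identical(s0$n, s15$n)
  expect_gt(s15$n_inflated, s15$n)
  expect_identical(s15$n_inflated, as.numeric(ceiling(s15$n / 0.85)))
})
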