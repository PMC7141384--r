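# Every cell of the seven-parameter early-warning rubric, as a
# parameterised case table: (scorer, input, expected weight).

rubric_cases <- list(
  # respiratory rate: <=8 -> 3, 9-11 -> 1, 12-20 -> 0, 21-24 -> 2, >=25 -> 3
  list(score_respiratory_rate, 4, 3), list(score_respiratory_rate, 8, 3),
  list(score_respiratory_rate, 9, 1), list(score_respiratory_rate, 11, 1),
  list(score_respiratory_rate, 12, 0), list(score_respiratory_rate, 16, 0),
  list(score_respiratory_rate, 20, 0), list(score_respiratory_rate, 21, 2),
  list(score_respiratory_rate, 22, 2), list(score_respiratory_rate, 24, 2),
  list(score_respiratory_rate, 25, 3), list(score_respiratory_rate, 40, 3),
  # heart rate: <=40 -> 3, 41-50 -> 1, 51-90 -> 0, 91-110 -> 1,
  # 111-130 -> 2, >=131 -> 3
  list(score_pulse, 40, 3), list(score_pulse, 41, 1), list(score_pulse, 50, 1),
  list(score_pulse, 51, 0), list(score_pulse, 71, 0), list(score_pulse, 90, 0),
  list(score_pulse, 91, 1), list(score_pulse, 110, 1),
  list(score_pulse, 111, 2), list(score_pulse, 120, 2),
  list(score_pulse, 130, 2), list(score_pulse, 131, 3),
  # temperature: <=35.0 -> 3, 35.1-36.0 -> 1, 36.1-38.0 -> 0,
  # 38.1-39.0 -> 1, >=39.1 -> 2
  list(score_temperature, 34.9, 3), list(score_temperature, 35.0, 3),
  list(score_temperature, 35.1, 1), list(score_temperature, 36.0, 1),
  list(score_temperature, 36.1, 0), list(score_temperature, 37.0, 0),
  list(score_temperature, 38.0, 0), list(score_temperature, 38.1, 1),
  list(score_temperature, 39.0, 1), list(score_temperature, 39.1, 2),
  # systolic blood pressure: <=90 -> 3, 91-100 -> 2, 101-110 -> 1,
  # 111-219 -> 0, >=220 -> 3
  list(score_systolic_bp, 90, 3), list(score_systolic_bp, 91, 2),
  list(score_systolic_bp, 100, 2), list(score_systolic_bp, 101, 1),
  list(score_systolic_bp, 105, 1), list(score_systolic_bp, 110, 1),
  list(score_systolic_bp, 111, 0), list(score_systolic_bp, 127, 0),
  list(score_systolic_bp, 219, 0), list(score_systolic_bp, 220, 3)
)

test_that("every rubric band cell scores its published weight", {
  for (case in rubric_cases) {
    expect_identical(case[[1]](case[[2]]), as.integer(case[[3]]),
                     label = sprintf("%s -> %d", deparse(case[[2]]),
                                     case[[3]]))
  }
  # oxygen saturation, scale 1 (supplemental oxygen must not enter)
  for (oxy in c(FALSE, TRUE)) {
    expect_identical(score_spo2(91, "scale1", oxy), 3L)
    expect_identical(score_spo2(92, "scale1", oxy), 2L)
    expect_identical(score_spo2(93, "scale1", oxy), 2L)
    expect_identical(score_spo2(94, "scale1", oxy), 1L)
    expect_identical(score_spo2(95, "scale1", oxy), 1L)
    expect_identical(score_spo2(96, "scale1", oxy), 0L)
    expect_identical(score_spo2(100, "scale1", oxy), 0L)
  }
  # oxygen saturation, scale 2
  expect_identical(score_spo2(83, "scale2"), 3L)
  expect_identical(score_spo2(84, "scale2"), 2L)
  expect_identical(score_spo2(85, "scale2"), 2L)
  expect_identical(score_spo2(86, "scale2"), 1L)
  expect_identical(score_spo2(87, "scale2"), 1L)
  expect_identical(score_spo2(88, "scale2"), 0L)
  expect_identical(score_spo2(92, "scale2"), 0L)
  # above 92 the weight depends on oxygen therapy
  expect_identical(score_spo2(93, "scale2", on_oxygen = FALSE), 0L)
  expect_identical(score_spo2(97, "scale2", on_oxygen = FALSE), 0L)
  expect_identical(score_spo2(93, "scale2", on_oxygen = TRUE), 1L)
  expect_identical(score_spo2(94, "scale2", on_oxygen = TRUE), 1L)
  expect_identical(score_spo2(95, "scale2", on_oxygen = TRUE), 2L)
  expect_identical(score_spo2(96, "scale2", on_oxygen = TRUE), 2L)
  expect_identical(score_spo2(97, "scale2", on_oxygen = TRUE), 3L)
  # supplemental oxygen and consciousness
  expect_identical(score_supplemental_oxygen(TRUE), 2L)
  expect_identical(score_supplemental_oxygen(FALSE), 0L)
  expect_identical(score_consciousness(gcs = 15), 0L)
  expect_identical(score_consciousness(gcs = 14), 3L)
  expect_identical(score_consciousness(gcs = 3), 3L)
  expect_identical(score_consciousness(avpu = "A"), 0L)
  expect_identical(score_consciousness(avpu = "V"), 3L)
  expect_identical(score_consciousness(avpu = "P"), 3L)
  expect_identical(score_consciousness(avpu = "U"), 3L)
})

test_that("bands partition each input domain", {
  # every grid value maps to exactly one weight in {0,1,2,3}; a shift of
  # one resolution step never skips a band boundary
  grids <- list(
    list(score_respiratory_rate, 0:80),
    list(score_pulse, 0:250),
    list(score_systolic_bp, 0:300),
    list(function(x) score_spo2(x, "scale1"), 0:100),
    list(function(x) score_spo2(x, "scale2", on_oxygen = TRUE), 0:100),
    list(function(x) score_spo2(x, "scale2", on_oxygen = FALSE), 0:100),
    list(score_temperature, seq(25, 45, by = 0.1))
  )
  for (g in grids) {
    s <- g[[1]](g[[2]])
    expect_true(all(s %in% 0:3))
    expect_length(s, length(g[[2]]))
  }
  expect_true(all(score_consciousness(gcs = 3:15) %in% c(0L, 3L)))
})

test_that("half-up rounding places boundary temperatures in the upper band", {
  expect_identical(score_temperature(38.05), 1L)  # rounds to 38.1
  expect_identical(score_temperature(38.04), 0L)  # rounds to 38.0
  expect_identical(score_temperature(35.04), 3L)  # rounds to 35.0
  expect_identical(score_temperature(35.05), 1L)  # rounds to 35.1
})

test_that("scorers reject out-of-domain input", {
  expect_error(score_respiratory_rate(-1), ">= 0")
  expect_error(score_spo2(101), "\\[0, 100\\]")
  expect_error(score_spo2(-5), "\\[0, 100\\]")
  expect_error(score_consciousness(gcs = 2), "\\[3, 15\\]")
  expect_error(score_consciousness(gcs = 16), "\\[3, 15\\]")
  expect_error(score_consciousness(gcs = 15, avpu = "A"), "exactly one")
  expect_error(score_consciousness(), "exactly one")
  expect_error(score_consciousness(avpu = "X"), "avpu")
})

test_that("full score aggregates the sub-scores with escalation flags", {
  all_normal <- news2(rr = 16, spo2 = 96, on_oxygen = FALSE, temp_c = 36.5,
                      sbp = 127, hr = 71, gcs = 15)
  expect_identical(all_normal$total, 0L)
  expect_false(all_normal$urgent_review)
  expect_false(all_normal$critical_review)

  mixed <- news2(rr = 22, spo2 = 93, on_oxygen = FALSE, temp_c = 35.7,
                 sbp = 105, hr = 82, gcs = 14)
  expect_identical(mixed$total, 9L)  # 2+2+0+1+1+0+3
  expect_true(mixed$any_single_three)
  expect_true(mixed$urgent_review)
  expect_true(mixed$critical_review)

  worst <- news2(rr = 8, spo2 = 83, on_oxygen = TRUE, temp_c = 34.9,
                 sbp = 90, hr = 40, gcs = 3, spo2_scale = "scale2")
  expect_identical(worst$total, 20L)  # the structural maximum

  # total always equals the sum of the sub-scores
  for (b in list(all_normal, mixed, worst)) {
    expect_identical(b$total, as.integer(rowSums(b[, 1:7])))
  }
})

test_that("a critical-review flag implies an urgent-review flag", {
  set.seed(11)
  b <- news2(rr = sample(0:40, 200, TRUE), spo2 = sample(80:100, 200, TRUE),
             on_oxygen = sample(c(TRUE, FALSE), 200, TRUE),
             temp_c = round(runif(200, 33, 41), 1),
             sbp = sample(60:230, 200, TRUE), hr = sample(30:150, 200, TRUE),
             gcs = sample(3:15, 200, TRUE))
  expect_true(all(b$total >= 0L & b$total <= 20L))
  expect_true(all(!b$critical_review | b$urgent_review))
})

test_that("the total is monotone when one parameter worsens", {
  set.seed(12)
  base <- list(rr = 16, spo2 = 97, on_oxygen = FALSE, temp_c = 37,
               sbp = 120, hr = 75, gcs = 15)
  worse <- list(rr = 30, spo2 = 85, on_oxygen = TRUE, temp_c = 34,
                sbp = 85, hr = 140, gcs = 10)
  for (param in names(base)) {
    args <- base
    args[[param]] <- worse[[param]]
    expect_gte(do.call(news2, args)$total,
               do.call(news2, base)$total)
  }
})

test_that("a missing vital is an error naming the field", {
  expect_error(news2(rr = NA, spo2 = 96, on_oxygen = FALSE, temp_c = 36.5,
                     sbp = 120, hr = 70, gcs = 15), "rr")
  expect_error(news2(rr = 16, spo2 = 96, on_oxygen = FALSE, temp_c = 36.5,
                     sbp = 120, hr = NA, gcs = 15), "hr")
  expect_error(news2(rr = 16, spo2 = 96, on_oxygen = FALSE, temp_c = 36.5,
                     sbp = 120, hr = 70), "consciousness")
})

test_that("the lactate composite is an exact unitless sum with range flag", {
  expect_equal(news2_l(0, 0.8)$news2_l, 0.8)
  expect_equal(news2_l(11, 5.2)$news2_l, 16.2)
  expect_equal(news2_l(3, 2.6)$news2_l, 5.6)
  # subtracting the lactate recovers the score exactly
  set.seed(13)
  tot <- sample(0:20, 100, TRUE)
  lact <- round(runif(100, 0.8, 21.7), 1)
  comp <- news2_l(tot, lact)
  expect_identical(comp$news2_l, tot + lact)  # the stored sum is exact
  expect_true(all(comp$lactate_in_range))
  # out-of-device-range lactate is flagged, not rejected
  expect_warning(flagged <- news2_l(5, 25), "measuring range")
  expect_false(flagged$lactate_in_range)
  expect_equal(flagged$news2_l, 30)
  expect_error(news2_l(5, 0), "positive")
  expect_error(news2_l(21, 1.0), "\\[0, 20\\]")
})
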