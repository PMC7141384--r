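#' @keywords internal
#' Round half away from zero at a fixed number of decimals.
#'
#' Base `round()` uses banker's rounding; the vital-sign rubric is stated at
#' fixed resolutions (integers, one decimal for temperature) with half-up
#' rounding, so 38.05 degrees must land on 38.1.  A small relative epsilon
#' absorbs binary representation error at the .x5 boundaries.
round_half_up <- function(x, digits = 0) {
  s <- x * 10^digits
  floor(s + 0.5 + sqrt(.Machine$double.eps) * abs(s)) / 10^digits
}

#' NEWS2 sub-score for respiratory rate
#'
#' Bands: <= 8 -> 3, 9-11 -> 1, 12-20 -> 0, 21-24 -> 2, >= 25 -> 3
#' (breaths/min).
#'
#' @param rr Respiratory rate in breaths per minute (non-negative).
#' @return Integer sub-score in \{0, 1, 2, 3\}, vectorised over `rr`.
#' @examples
#' score_respiratory_rate(c(8, 16, 22, 30))
#' @export
score_respiratory_rate <- function(rr) {
  rr <- round_half_up(rr)
  stopifnot("respiratory rate must be non-missing" = !anyNA(rr))
  if (any(rr < 0)) stop("respiratory rate must be >= 0")
  ifelse(rr <= 8, 3L,
  ifelse(rr <= 11, 1L,
  ifelse(rr <= 20, 0L,
  ifelse(rr <= 24, 2L, 3L))))
}

#' NEWS2 sub-score for oxygen saturation
#'
#' Scale 1 (default): <= 91 -> 3, 92-93 -> 2, 94-95 -> 1, >= 96 -> 0;
#' supplemental oxygen does not enter (it is scored separately).
#' Scale 2 (for patients with diagnosed hypercapnic respiratory
#' insufficiency): <= 83 -> 3, 84-85 -> 2, 86-87 -> 1, 88-92 -> 0; above 92
#' the weight depends on oxygen therapy: on air -> 0, on oxygen 93-94 -> 1,
#' 95-96 -> 2, >= 97 -> 3.
#'
#' @param spo2 Peripheral oxygen saturation in percent, 0-100.
#' @param scale `"scale1"` or `"scale2"`; which saturation rubric applies.
#'   Scale 2 is a clinical flag set per patient, never inferred from the
#'   saturation value itself.
#' @param on_oxygen Logical; is the patient on supplemental oxygen?
#' @return Integer sub-score in \{0, 1, 2, 3\}.
#' @examples
#' score_spo2(93, "scale1")
#' score_spo2(96, "scale2", on_oxygen = TRUE)
#' @export
score_spo2 <- function(spo2, scale = c("scale1", "scale2"), on_oxygen = FALSE) {
  if (identical(scale, c("scale1", "scale2"))) scale <- "scale1"
  scale <- tolower(as.character(scale))
  if (anyNA(scale) || !all(scale %in% c("scale1", "scale2"))) {
    stop("spo2_scale must be 'scale1' or 'scale2'")
  }
  spo2 <- round_half_up(spo2)
  stopifnot("spo2 must be non-missing" = !anyNA(spo2))
  if (any(spo2 < 0 | spo2 > 100)) stop("spo2 must be within [0, 100]")
  n <- max(length(spo2), length(scale), length(on_oxygen))
  spo2 <- rep_len(spo2, n)
  scale <- rep_len(scale, n)
  on_oxygen <- rep_len(as.logical(on_oxygen), n)
  s1 <- ifelse(spo2 <= 91, 3L,
        ifelse(spo2 <= 93, 2L,
        ifelse(spo2 <= 95, 1L, 0L)))
  s2 <- ifelse(spo2 <= 83, 3L,
        ifelse(spo2 <= 85, 2L,
        ifelse(spo2 <= 87, 1L,
        ifelse(spo2 <= 92, 0L,
        # above 92: weight only under oxygen therapy
        ifelse(!on_oxygen, 0L,
        ifelse(spo2 <= 94, 1L,
        ifelse(spo2 <= 96, 2L, 3L)))))))
  ifelse(scale == "scale2", s2, s1)
}

#' NEWS2 sub-score for supplemental oxygen
#'
#' Any supplemental oxygen scores 2; breathing air scores 0.
#'
#' @param on_oxygen Logical.
#' @return Integer sub-score in \{0, 2\}.
#' @export
score_supplemental_oxygen <- function(on_oxygen) {
  on_oxygen <- as.logical(on_oxygen)
  stopifnot("on_oxygen must be non-missing" = !anyNA(on_oxygen))
  ifelse(on_oxygen, 2L, 0L)
}

#' NEWS2 sub-score for temperature
#'
#' Bands (degrees Celsius, one-decimal resolution): <= 35.0 -> 3,
#' 35.1-36.0 -> 1, 36.1-38.0 -> 0, 38.1-39.0 -> 1, >= 39.1 -> 2.
#' Inputs are rounded half-up to one decimal first, so the rubric's apparent
#' gaps (e.g. 38.0 to 38.1) cannot be hit.
#'
#' @param temp_c Tympanic temperature in degrees Celsius.
#' @return Integer sub-score in \{0, 1, 2, 3\}.
#' @export
score_temperature <- function(temp_c) {
  stopifnot("temperature must be non-missing" = !anyNA(temp_c))
  # work in tenths of a degree to keep the comparisons exact
  t10 <- round_half_up(temp_c * 10)
  ifelse(t10 <= 350, 3L,
  ifelse(t10 <= 360, 1L,
  ifelse(t10 <= 380, 0L,
  ifelse(t10 <= 390, 1L, 2L))))
}

#' NEWS2 sub-score for systolic blood pressure
#'
#' Bands (mmHg): <= 90 -> 3, 91-100 -> 2, 101-110 -> 1, 111-219 -> 0,
#' >= 220 -> 3.
#'
#' @param sbp Systolic blood pressure in mmHg (non-negative).
#' @return Integer sub-score in \{0, 1, 2, 3\}.
#' @export
score_systolic_bp <- function(sbp) {
  sbp <- round_half_up(sbp)
  stopifnot("systolic blood pressure must be non-missing" = !anyNA(sbp))
  if (any(sbp < 0)) stop("systolic blood pressure must be >= 0")
  ifelse(sbp <= 90, 3L,
  ifelse(sbp <= 100, 2L,
  ifelse(sbp <= 110, 1L,
  ifelse(sbp <= 219, 0L, 3L))))
}

#' NEWS2 sub-score for heart rate
#'
#' Bands (beats/min): <= 40 -> 3, 41-50 -> 1, 51-90 -> 0, 91-110 -> 1,
#' 111-130 -> 2, >= 131 -> 3.
#'
#' @param hr Heart rate in beats per minute (non-negative).
#' @return Integer sub-score in \{0, 1, 2, 3\}.
#' @export
score_pulse <- function(hr) {
  hr <- round_half_up(hr)
  stopifnot("heart rate must be non-missing" = !anyNA(hr))
  if (any(hr < 0)) stop("heart rate must be >= 0")
  ifelse(hr <= 40, 3L,
  ifelse(hr <= 50, 1L,
  ifelse(hr <= 90, 0L,
  ifelse(hr <= 110, 1L,
  ifelse(hr <= 130, 2L, 3L)))))
}

#' NEWS2 sub-score for level of consciousness
#'
#' Alert (AVPU "A", equivalently GCS 15) scores 0; any altered consciousness
#' (AVPU "V", "P" or "U", equivalently GCS below 15, the study's definition
#' of confusion) scores 3.  Supply exactly one of `gcs` or `avpu`.
#'
#' @param gcs Glasgow Coma Scale total, integer 3-15.
#' @param avpu One of `"A"`, `"V"`, `"P"`, `"U"`.
#' @return Integer sub-score in \{0, 3\}.
#' @examples
#' score_consciousness(gcs = 15)
#' score_consciousness(avpu = "U")
#' @export
score_consciousness <- function(gcs = NULL, avpu = NULL) {
  if (is.null(gcs) == is.null(avpu)) {
    stop("supply exactly one of 'gcs' or 'avpu'")
  }
  if (!is.null(gcs)) {
    gcs <- round_half_up(gcs)
    stopifnot("gcs must be non-missing" = !anyNA(gcs))
    if (any(gcs < 3 | gcs > 15)) stop("gcs must be within [3, 15]")
    return(ifelse(gcs == 15, 0L, 3L))
  }
  avpu <- toupper(as.character(avpu))
  stopifnot("avpu must be non-missing" = !anyNA(avpu))
  if (!all(avpu %in% c("A", "V", "P", "U"))) {
    stop("avpu must be one of 'A', 'V', 'P', 'U'")
  }
  ifelse(avpu == "A", 0L, 3L)
}

#' Compute the NEWS2 from one or more vital-sign observation sets
#'
#' Applies the seven-parameter early-warning rubric (respiratory rate,
#' oxygen saturation, supplemental oxygen, temperature, systolic blood
#' pressure, heart rate, consciousness) and returns per-parameter
#' sub-scores, the total (0-20) and the escalation flags: a total above 5,
#' or a 3 in any single parameter, triggers an urgent review; a total above
#' 7 triggers a critical-care review.
#'
#' All vitals must be present; a missing value is an error naming the field
#' (incomplete vital-sign sets cannot be scored).  Use [score_cohort()] to
#' score a cohort table while excluding incomplete rows.
#'
#' @param rr Respiratory rate, breaths/min.
#' @param spo2 Oxygen saturation, percent.
#' @param on_oxygen Logical, supplemental oxygen in use.
#' @param temp_c Temperature, degrees Celsius.
#' @param sbp Systolic blood pressure, mmHg.
#' @param hr Heart rate, beats/min.
#' @param gcs,avpu Consciousness, exactly one supplied (see
#'   [score_consciousness()]).
#' @param spo2_scale `"scale1"` (default) or `"scale2"`; see [score_spo2()].
#' @return A `data.frame` of class `"news2_breakdown"` with one row per
#'   observation and columns `rr`, `spo2`, `oxygen`, `temp`, `sbp`, `hr`,
#'   `consciousness` (the sub-scores), `total`, `any_single_three`,
#'   `urgent_review`, `critical_review`.
#' @examples
#' news2(rr = 22, spo2 = 93, on_oxygen = FALSE, temp_c = 35.7,
#'       sbp = 105, hr = 82, gcs = 14)
#' @export
news2 <- function(rr, spo2, on_oxygen, temp_c, sbp, hr,
                  gcs = NULL, avpu = NULL, spo2_scale = "scale1") {
  fields <- list(rr = rr, spo2 = spo2, on_oxygen = on_oxygen,
                 temp_c = temp_c, sbp = sbp, hr = hr)
  if (is.null(gcs) && is.null(avpu)) {
    stop("missing vital sign: consciousness (gcs or avpu)")
  }
  fields$consciousness <- if (is.null(gcs)) avpu else gcs
  for (nm in names(fields)) {
    if (length(fields[[nm]]) == 0L || anyNA(fields[[nm]])) {
      stop("missing vital sign: ", nm)
    }
  }
  sub <- data.frame(
    rr            = score_respiratory_rate(rr),
    spo2          = score_spo2(spo2, spo2_scale, on_oxygen),
    oxygen        = score_supplemental_oxygen(on_oxygen),
    temp          = score_temperature(temp_c),
    sbp           = score_systolic_bp(sbp),
    hr            = score_pulse(hr),
    consciousness = score_consciousness(gcs = gcs, avpu = avpu)
  )
  sub$total <- as.integer(rowSums(sub))
  sub$any_single_three <- apply(sub[, 1:7, drop = FALSE] == 3L, 1L, any)
  sub$urgent_review <- sub$total > 5L | sub$any_single_three
  sub$critical_review <- sub$total > 7L
  class(sub) <- c("news2_breakdown", class(sub))
  sub
}

#' NEWS2-L composite score
#'
#' Adds the numerical point-of-care lactate value (mmol/L) to the NEWS2
#' total, giving a unitless composite.  Lactate values outside the
#' point-of-care device measuring range (0.8-21.7 mmol/L) are accepted but
#' flagged, so heavy-tailed synthetic cohorts remain scorable.
#'
#' @param news2_total NEWS2 total score in points (0-20).
#' @param lactate Venous lactate in mmol/L; must be positive.
#' @param device_range Length-2 numeric, the measuring range of the lactate
#'   device used for the out-of-range flag.
#' @return A `data.frame` with columns `news2`, `lactate`, `news2_l` and
#'   `lactate_in_range`.
#' @examples
#' news2_l(11, 5.2)
#' @export
news2_l <- function(news2_total, lactate, device_range = c(0.8, 21.7)) {
  stopifnot(
    "news2_total must be non-missing" = !anyNA(news2_total),
    "lactate must be non-missing" = !anyNA(lactate),
    length(device_range) == 2L
  )
  if (any(news2_total < 0 | news2_total > 20)) {
    stop("news2_total must be within [0, 20]")
  }
  if (any(lactate <= 0)) stop("lactate must be positive (mmol/L)")
  in_range <- lactate >= device_range[1] & lactate <= device_range[2]
  if (!all(in_range)) {
    warning(sum(!in_range),
            " lactate value(s) outside the device measuring range [",
            device_range[1], ", ", device_range[2], "] mmol/L; flagged")
  }
  data.frame(news2 = news2_total, lactate = lactate,
             news2_l = news2_total + lactate,
             lactate_in_range = in_range)
}

#' @export
print.news2_breakdown <- function(x, ...) {
  cat("NEWS2 breakdown (", nrow(x), " observation",
      if (nrow(x) != 1) "s", ")\n", sep = "")
  NextMethod()
  invisible(x)
}
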