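#' Default class-conditional distribution specifications
#'
#' The survivor / non-survivor (48-h mortality) median and IQR targets for
#' each generated variable, as published for the 361-patient prehospital
#' syncope cohort the generator emulates.  Right-skewed positive variables
#' (respiratory rate, lactate) use the lognormal family; roughly symmetric
#' bounded vitals (saturation, temperature, blood pressure, heart rate,
#' age) use truncated normals with hard physiological bounds.
#'
#' @return A named list; each element has `survivor` and `nonsurvivor`
#'   [quantile_spec()]s plus a `digits` rounding resolution.
#' @export
default_variable_specs <- function() {
  list(
    age = list(
      survivor = quantile_spec(74, 62, 83, "truncnorm", 18, 105),
      nonsurvivor = quantile_spec(81, 73, 87, "truncnorm", 18, 105),
      digits = 0),
    rr = list(
      survivor = quantile_spec(16, 12, 19, "lognormal", 4, 60),
      nonsurvivor = quantile_spec(20, 16, 32, "lognormal", 4, 80),
      digits = 0),
    spo2 = list(
      survivor = quantile_spec(96, 94, 98, "truncnorm", 40, 100),
      nonsurvivor = quantile_spec(89, 76, 94, "truncnorm", 40, 100),
      digits = 0),
    temp_c = list(
      survivor = quantile_spec(36.1, 35.8, 36.6, "truncnorm", 30, 42),
      nonsurvivor = quantile_spec(35.7, 34.9, 36.2, "truncnorm", 30, 42),
      digits = 1),
    sbp = list(
      survivor = quantile_spec(128, 108, 144, "truncnorm", 40, 260),
      nonsurvivor = quantile_spec(105, 84, 139, "truncnorm", 40, 260),
      digits = 0),
    hr = list(
      survivor = quantile_spec(70, 57, 87, "truncnorm", 20, 220),
      nonsurvivor = quantile_spec(82, 40, 96, "truncnorm", 20, 220),
      digits = 0),
    lactate = list(
      survivor = quantile_spec(2.6, 1.8, 3.6, "lognormal", 0.1, 30),
      nonsurvivor = quantile_spec(5.2, 4.5, 6.6, "lognormal", 0.1, 30),
      digits = 1)
  )
}

# per-class electrocardiographic rhythm frequencies (descriptive only)
ecg_rhythm_levels <- c("sinus", "sinus_bradycardia", "sinus_tachycardia",
                       "atrial_fibrillation", "av_block", "pacemaker")

default_ecg_probs <- function() {
  list(survivor = c(192, 46, 33, 34, 24, 11) / 340,
       nonsurvivor = c(5, 1, 7, 1, 6, 1) / 21)
}

#' Synthetic cohort specification
#'
#' Collects every parameter of the seeded two-class cohort generator: the
#' cohort size, the 48-h mortality rate, class-conditional distribution
#' specs for each vital sign and lactate, conditional outcome rates, the
#' consciousness (GCS) model, supplemental-oxygen rates, and the
#' saturation/respiratory-rate copula correlation.
#'
#' The defaults reproduce the published cohort margins: mortality 5.8%;
#' prehospital advanced life support in 76.2% of non-survivors and 10.3% of
#' survivors (14.1% overall); ICU admission in 52.4% of non-survivors and
#' 5.9% of survivors (8.6% overall); all non-survivors admitted.  The GCS
#' model and the supplemental-oxygen rates are not published; the defaults
#' (survivors: GCS 15 with probability 0.95, oxygen 8%; non-survivors: a
#' clipped Normal(14, 9) rounded to integer GCS, oxygen 60%) are clinically
#' plausible values under which the computed NEWS2 class margins match the
#' published ones (median 3 vs 11).
#'
#' @param n Cohort size (>= 20).
#' @param mortality_rate 48-h mortality fraction.
#' @param pals_given_death,pals_given_survival Conditional advanced-life-
#'   support rates.
#' @param icu_given_death,icu_given_survival Conditional ICU rates.
#' @param admitted_given_survival Hospital-admission rate among survivors
#'   (non-survivors are always admitted).
#' @param female_fraction Fraction of women.
#' @param oxygen_given_death,oxygen_given_survival Supplemental-oxygen
#'   rates by class.
#' @param gcs15_given_survival Probability a survivor is fully alert
#'   (GCS 15); the small remainder is confused or worse.
#' @param gcs_nonsurvivor_mean,gcs_nonsurvivor_sd Normal parameters for the
#'   non-survivor GCS before rounding and clipping to \[3, 15\].
#' @param copula_rho Gaussian-copula correlation between oxygen saturation
#'   and respiratory rate within each class (negative: hypoxic patients
#'   breathe faster).
#' @param variables Class-conditional [quantile_spec()]s, as from
#'   [default_variable_specs()].
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n = 361,
                        mortality_rate = 0.058,
                        pals_given_death = 16 / 21,
                        pals_given_survival = 35 / 340,
                        icu_given_death = 11 / 21,
                        icu_given_survival = 20 / 340,
                        admitted_given_survival = 116 / 340,
                        female_fraction = 0.454,
                        oxygen_given_death = 0.60,
                        oxygen_given_survival = 0.08,
                        gcs15_given_survival = 0.95,
                        gcs_nonsurvivor_mean = 14,
                        gcs_nonsurvivor_sd = 9,
                        copula_rho = -0.4,
                        variables = default_variable_specs(),
                        seed = 1L) {
  rates <- c(mortality_rate, pals_given_death, pals_given_survival,
             icu_given_death, icu_given_survival, admitted_given_survival,
             female_fraction, oxygen_given_death, oxygen_given_survival,
             gcs15_given_survival)
  stopifnot(n >= 20, all(rates >= 0 & rates <= 1),
            abs(copula_rho) < 1, gcs_nonsurvivor_sd > 0)
  spec <- list(n = as.integer(n), mortality_rate = mortality_rate,
               pals_given_death = pals_given_death,
               pals_given_survival = pals_given_survival,
               icu_given_death = icu_given_death,
               icu_given_survival = icu_given_survival,
               admitted_given_survival = admitted_given_survival,
               female_fraction = female_fraction,
               oxygen_given_death = oxygen_given_death,
               oxygen_given_survival = oxygen_given_survival,
               gcs15_given_survival = gcs15_given_survival,
               gcs_nonsurvivor_mean = gcs_nonsurvivor_mean,
               gcs_nonsurvivor_sd = gcs_nonsurvivor_sd,
               copula_rho = copula_rho,
               variables = variables,
               ecg_probs = default_ecg_probs(),
               # class-conditional NEWS2 calibration references (computed
               # from vitals, never sampled): median (q25-q75)
               news2_targets = list(survivor = c(3, 1, 5),
                                    nonsurvivor = c(11, 6, 15)),
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

# draw one class's variables for n patients; fits is a named list of
# quantile_fit objects for that class
sample_class_variables <- function(n, fits, digits, rho) {
  out <- list()
  # SpO2 and respiratory rate share a Gaussian copula so hypoxia and
  # tachypnoea co-occur; the remaining vitals are conditionally
  # independent given the class.
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  out$spo2 <- quantile_fn(stats::pnorm(z1), fits$spo2)
  out$rr <- quantile_fn(stats::pnorm(z2), fits$rr)
  for (nm in setdiff(names(fits), c("spo2", "rr"))) {
    out[[nm]] <- sample_fit(n, fits[[nm]])
  }
  for (nm in names(out)) out[[nm]] <- round_half_up(out[[nm]], digits[[nm]])
  out
}

#' Generate a seeded synthetic syncope cohort
#'
#' Draws `spec$n` patient records: the 48-h outcome class first
#' (Bernoulli), then class-conditional vitals and lactate from the fitted
#' quantile distributions (rounded to rubric resolution and clipped to hard
#' physiological bounds), consciousness from the class GCS model,
#' supplemental oxygen, sex, electrocardiographic rhythm, and the secondary
#' outcomes (advanced life support, ICU, admission) from their conditional
#' rates.  The NEWS2 is *not* sampled — it is always computed from the
#' generated vitals via [news2()], so the deterministic score/vital
#' relationship is preserved.
#'
#' The generator is fully deterministic for a fixed spec (the seed is part
#' of the spec); the caller's RNG state is left untouched.
#'
#' @param spec A [cohort_spec()].
#' @return A `data.frame` with the cohort schema columns (`patient_id`,
#'   `age`, `sex`, `rr`, `spo2`, `on_oxygen`, `spo2_scale`, `temp_c`,
#'   `sbp`, `hr`, `gcs`, `lactate`, `death_48h`, `pals`, `icu`, `admitted`,
#'   `ecg_rhythm`) and the spec attached as attribute `"spec"`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 100, seed = 42))
#' table(cohort$death_48h)
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)
  n <- spec$n
  death <- stats::rbinom(n, 1L, spec$mortality_rate)

  fits <- lapply(c(survivor = "survivor", nonsurvivor = "nonsurvivor"),
                 function(cl) lapply(spec$variables, function(v) {
                   fit_quantiles(v[[cl]])
                 }))
  digits <- lapply(spec$variables, `[[`, "digits")

  cohort <- data.frame(patient_id = sprintf("SYN%05d", seq_len(n)))
  vars <- names(spec$variables)
  for (nm in vars) cohort[[nm]] <- NA_real_
  for (cl in c("survivor", "nonsurvivor")) {
    idx <- which(death == (cl == "nonsurvivor"))
    if (length(idx) == 0L) next
    drawn <- sample_class_variables(length(idx), fits[[cl]], digits,
                                    spec$copula_rho)
    for (nm in vars) cohort[[nm]][idx] <- drawn[[nm]]
  }

  # consciousness: survivors are almost always alert; non-survivor GCS is
  # a rounded clipped normal reproducing the published median/IQR
  gcs <- integer(n)
  surv_idx <- which(death == 0L)
  dead_idx <- which(death == 1L)
  if (length(surv_idx)) {
    alert <- stats::runif(length(surv_idx)) < spec$gcs15_given_survival
    tail_gcs <- sample(c(14L, 13L, 8L), length(surv_idx),
                       replace = TRUE, prob = c(0.6, 0.25, 0.15))
    gcs[surv_idx] <- ifelse(alert, 15L, tail_gcs)
  }
  if (length(dead_idx)) {
    raw <- stats::rnorm(length(dead_idx), spec$gcs_nonsurvivor_mean,
                        spec$gcs_nonsurvivor_sd)
    gcs[dead_idx] <- as.integer(pmin(15, pmax(3, round_half_up(raw))))
  }
  cohort$gcs <- gcs

  p_o2 <- ifelse(death == 1L, spec$oxygen_given_death,
                 spec$oxygen_given_survival)
  cohort$on_oxygen <- stats::runif(n) < p_o2
  cohort$spo2_scale <- "scale1"
  cohort$sex <- ifelse(stats::runif(n) < spec$female_fraction,
                       "female", "male")
  cohort$death_48h <- death
  cohort$pals <- as.integer(stats::runif(n) <
    ifelse(death == 1L, spec$pals_given_death, spec$pals_given_survival))
  cohort$icu <- as.integer(stats::runif(n) <
    ifelse(death == 1L, spec$icu_given_death, spec$icu_given_survival))
  cohort$admitted <- as.integer(
    death == 1L | stats::runif(n) < spec$admitted_given_survival)

  rhythm <- character(n)
  for (cl in c("survivor", "nonsurvivor")) {
    idx <- which(death == (cl == "nonsurvivor"))
    if (length(idx)) {
      rhythm[idx] <- sample(ecg_rhythm_levels, length(idx), replace = TRUE,
                            prob = spec$ecg_probs[[cl]])
    }
  }
  cohort$ecg_rhythm <- rhythm

  cohort <- cohort[, cohort_schema_columns()]
  attr(cohort, "spec") <- spec
  cohort
}

cohort_schema_columns <- function() {
  c("patient_id", "age", "sex", "rr", "spo2", "on_oxygen", "spo2_scale",
    "temp_c", "sbp", "hr", "gcs", "lactate", "death_48h", "pals", "icu",
    "admitted", "ecg_rhythm")
}

#' Score a cohort table
#'
#' Adds NEWS2 sub-totals, escalation flags and the NEWS2-L composite to a
#' cohort table.  Rows with any missing vital sign cannot be scored; they
#' are kept in the table with `NA` scores and counted in the
#' `"n_excluded"` attribute (mirroring the exclusion of incomplete
#' vital-sign sets from the analysis).
#'
#' @param cohort A cohort `data.frame` in the schema of
#'   [generate_cohort()] / [read_cohort()].
#' @return The cohort with added columns `news2`, `any_single_three`,
#'   `urgent_review`, `critical_review`, `news2_l`, `lactate_in_range`.
#' @export
score_cohort <- function(cohort) {
  needed <- c("rr", "spo2", "on_oxygen", "spo2_scale", "temp_c", "sbp",
              "hr", "gcs", "lactate")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  vital_cols <- setdiff(needed, "lactate")
  complete <- stats::complete.cases(cohort[vital_cols])
  n_excl <- sum(!complete)
  if (n_excl > 0) {
    message(n_excl, " row(s) with incomplete vital signs excluded from scoring")
  }
  cohort$news2 <- NA_integer_
  cohort$any_single_three <- NA
  cohort$urgent_review <- NA
  cohort$critical_review <- NA
  cohort$news2_l <- NA_real_
  cohort$lactate_in_range <- NA
  if (any(complete)) {
    cc <- cohort[complete, ]
    br <- news2(rr = cc$rr, spo2 = cc$spo2, on_oxygen = cc$on_oxygen,
                temp_c = cc$temp_c, sbp = cc$sbp, hr = cc$hr, gcs = cc$gcs,
                spo2_scale = cc$spo2_scale)
    cohort$news2[complete] <- br$total
    cohort$any_single_three[complete] <- br$any_single_three
    cohort$urgent_review[complete] <- br$urgent_review
    cohort$critical_review[complete] <- br$critical_review
    with_lact <- complete & !is.na(cohort$lactate)
    if (any(with_lact)) {
      comp <- news2_l(cohort$news2[with_lact], cohort$lactate[with_lact])
      cohort$news2_l[with_lact] <- comp$news2_l
      cohort$lactate_in_range[with_lact] <- comp$lactate_in_range
    }
  }
  attr(cohort, "n_excluded") <- n_excl
  cohort
}

#' Compare a generated cohort against its calibration targets
#'
#' For each generated variable and each outcome class, reports the
#' empirical median and quartiles next to the spec's targets and the
#' relative deviation of the median.  The computed NEWS2 is included as a
#' calibration *check* (its class targets are published cohort margins, not
#' sampling targets).  A cohort containing a single class is reported with
#' the missing class flagged as `NA`.
#'
#' @param cohort A cohort from [generate_cohort()] (scored or not).
#' @param spec The generating [cohort_spec()]; defaults to the one attached
#'   to the cohort.
#' @return A `data.frame` with one row per variable per class.
#' @export
calibration_report <- function(cohort, spec = attr(cohort, "spec")) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!"news2" %in% names(cohort)) cohort <- score_cohort(cohort)
  rows <- list()
  for (cl in c("survivor", "nonsurvivor")) {
    idx <- cohort$death_48h == (cl == "nonsurvivor")
    sub <- cohort[idx, ]
    targets <- c(lapply(spec$variables, function(v) {
      s <- v[[cl]]
      c(s$median, s$q25, s$q75)
    }), list(news2 = spec$news2_targets[[cl]]))
    for (nm in names(targets)) {
      tg <- targets[[nm]]
      if (nrow(sub) == 0L || all(is.na(sub[[nm]]))) {
        q <- c(NA_real_, NA_real_, NA_real_)
      } else {
        q <- unname(stats::quantile(sub[[nm]], c(0.5, 0.25, 0.75),
                                    na.rm = TRUE, type = 7))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = nm, class = cl, n = nrow(sub),
        median = q[1], q25 = q[2], q75 = q[3],
        target_median = tg[1], target_q25 = tg[2], target_q75 = tg[3],
        rel_dev_median = abs(q[1] - tg[1]) / abs(tg[1]),
        missing_class = nrow(sub) == 0L)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write a cohort CSV
#'
#' The cohort schema has fixed, case-insensitive column names:
#' `patient_id, age, sex, rr, spo2, on_oxygen, spo2_scale, temp_c, sbp,
#' hr, gcs, lactate, death_48h, pals, icu, admitted, ecg_rhythm`.  Missing
#' vitals are encoded as empty fields.  An empty `spo2_scale` defaults to
#' `"scale1"`.
#'
#' @param path File path.
#' @return `read_cohort()`: the cohort `data.frame`; `write_cohort()`: the
#'   path, invisibly.
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, strip.white = TRUE, stringsAsFactors = FALSE)
  names(x) <- tolower(names(x))
  missing_cols <- setdiff(cohort_schema_columns(), names(x))
  if (length(missing_cols)) {
    stop("cohort CSV is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  x$on_oxygen <- coerce_logical(x$on_oxygen)
  x$spo2_scale[is.na(x$spo2_scale) | x$spo2_scale == ""] <- "scale1"
  x$spo2_scale <- tolower(x$spo2_scale)
  for (col in c("age", "rr", "spo2", "temp_c", "sbp", "hr", "gcs",
                "lactate")) {
    x[[col]] <- as.numeric(x[[col]])
  }
  for (col in c("death_48h", "pals", "icu", "admitted")) {
    x[[col]] <- as.integer(x[[col]])
  }
  x
}

# permissive logical coercion for CSV columns (0/1, true/false, yes/no)
coerce_logical <- function(v) {
  if (is.logical(v)) return(v)
  if (is.numeric(v)) return(v != 0)
  v <- tolower(trimws(as.character(v)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' @rdname read_cohort
#' @param cohort A cohort `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort[, intersect(names(cohort),
                                      c(cohort_schema_columns(),
                                        "news2", "news2_l",
                                        "any_single_three", "urgent_review",
                                        "critical_review",
                                        "lactate_in_range"))],
                   path, row.names = FALSE)
  invisible(path)
}
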