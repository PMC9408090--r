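#' The eight health conditions
#'
#' Canonical machine names (and printable labels) for the eight health
#' conditions and lifestyle risks a worker is classified against: poor sleep,
#' risky alcohol use, current smoking, poor diet, weight problem (BMI outside
#' the healthy band), insufficient physical activity, poor physical health
#' and psychological distress.
#'
#' @return `risk_conditions()` returns a character vector of the eight
#'   condition names; `condition_labels()` returns a named character vector
#'   mapping those names to human-readable table labels.
#' @export
#' @examples
#' risk_conditions()
risk_conditions <- function() {
  c("poor_sleep", "risky_alcohol", "smoking", "poor_diet",
    "weight_problem", "insufficient_pa", "poor_physical_health",
    "psychological_distress")
}

#' @rdname risk_conditions
#' @export
condition_labels <- function() {
  c(poor_sleep             = "Poor sleep condition",
    risky_alcohol          = "Risky alcohol use",
    smoking                = "Smoking",
    poor_diet              = "Poor diet",
    weight_problem         = "Weight problems",
    insufficient_pa        = "Insufficient physical activity",
    poor_physical_health   = "Poor physical health",
    psychological_distress = "Psychological distress")
}

#' Sleep quality response levels
#'
#' Five-level ordinal scale, best to worst. The worst two levels ("fairly
#' bad", "very bad") count towards the poor-sleep classification.
#'
#' @return Character vector of the five levels.
#' @export
sleep_quality_levels <- function() {
  c("very good", "good", "fair", "fairly bad", "very bad")
}

#' Smoking status levels
#' @return Character vector of the three levels.
#' @export
smoking_levels <- function() c("never", "previous", "current")

#' High/low risk classification thresholds
#'
#' Bundles the instrument cut-points used to classify each worker as high or
#' low risk for each condition. Defaults follow the established screening
#' conventions for each instrument: K10 >= 22 for psychological distress,
#' SF-8 PCS < 50 for poor physical health, sleep < 7 h and/or bad quality,
#' AUDIT-C >= 4 (men) / >= 3 (women), current smoking, < 600 MET-minutes per
#' week, BMI outside [18.5, 25), and fewer than 2 fruit and/or 5 vegetable
#' serves per day.
#'
#' @param k10_high_min Minimum K10 score (10-50 scale) flagged as high
#'   psychological distress. Default 22.
#' @param pcs_high_max PCS threshold; scores strictly below are flagged as
#'   poor physical health. Default 50.
#' @param sleep_hours_min Minimum nightly sleep hours; fewer is flagged.
#'   Default 7.
#' @param auditc_high_min_male,auditc_high_min_female Minimum AUDIT-C score
#'   (0-12) flagged as risky drinking, by sex. Defaults 4 and 3.
#' @param met_min_per_week Minimum weekly MET-minutes; fewer is flagged as
#'   insufficient activity. Default 600.
#' @param bmi_low,bmi_normal_max Healthy BMI band `[bmi_low, bmi_normal_max)`;
#'   outside is flagged as a weight problem. Defaults 18.5 and 25.
#' @param fruit_min,veg_min Minimum daily serves of fruit and vegetables;
#'   below either is flagged as poor diet. Defaults 2 and 5.
#' @return A list of thresholds with class `"risk_rules"`.
#' @export
#' @examples
#' risk_rules()
#' risk_rules(k10_high_min = 25)
risk_rules <- function(k10_high_min = 22,
                       pcs_high_max = 50,
                       sleep_hours_min = 7,
                       auditc_high_min_male = 4,
                       auditc_high_min_female = 3,
                       met_min_per_week = 600,
                       bmi_low = 18.5,
                       bmi_normal_max = 25,
                       fruit_min = 2,
                       veg_min = 5) {
  rules <- list(
    k10_high_min = k10_high_min,
    pcs_high_max = pcs_high_max,
    sleep_hours_min = sleep_hours_min,
    auditc_high_min_male = auditc_high_min_male,
    auditc_high_min_female = auditc_high_min_female,
    met_min_per_week = met_min_per_week,
    bmi_low = bmi_low,
    bmi_normal_max = bmi_normal_max,
    fruit_min = fruit_min,
    veg_min = veg_min
  )
  bad <- names(rules)[!vapply(rules, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("risk_rules thresholds must be single positive numbers: ",
                 paste(bad, collapse = ", ")))
  }
  if (rules$bmi_low >= rules$bmi_normal_max) {
    abort("`bmi_low` must be below `bmi_normal_max`")
  }
  structure(rules, class = "risk_rules")
}

check_range <- function(x, lo, hi, what) {
  bad <- !is.na(x) & (x < lo | x > hi)
  if (any(bad)) {
    abort(sprintf("%s must be in [%s, %s]; got %s", what, format(lo),
                  format(hi), paste(head(unique(x[bad]), 3), collapse = ", ")))
  }
  invisible(x)
}

check_nonneg <- function(x, what) {
  bad <- !is.na(x) & x < 0
  if (any(bad)) abort(sprintf("%s must be non-negative", what))
  invisible(x)
}

check_levels <- function(x, levels, what) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    abort(sprintf("%s must be one of: %s (got %s)", what,
                  paste(levels, collapse = ", "),
                  paste(head(unique(x[bad]), 3), collapse = ", ")))
  }
  invisible(x)
}

#' Classify psychological distress from the K10 score
#'
#' High risk is a Kessler-10 total of `k10_high_min` (default 22) or above,
#' covering the conventional "high" (22-29) and "very high" (30-50) bands.
#'
#' @param k10_score Integer K10 total in 10-50. `NA` propagates.
#' @param rules A [risk_rules()] object.
#' @return Logical vector: `TRUE` = high risk.
#' @export
#' @examples
#' classify_psychological_distress(c(10, 21, 22, 50))
classify_psychological_distress <- function(k10_score, rules = risk_rules()) {
  check_range(k10_score, 10, 50, "`k10_score`")
  k10_score >= rules$k10_high_min
}

#' Classify physical health from the SF-8 PCS score
#'
#' High risk (poor physical health) is a physical component summary score
#' strictly below `pcs_high_max` (default 50).
#'
#' @param pcs_score PCS score in 0-100.
#' @inheritParams classify_psychological_distress
#' @return Logical vector: `TRUE` = poor physical health.
#' @export
classify_physical_health <- function(pcs_score, rules = risk_rules()) {
  check_range(pcs_score, 0, 100, "`pcs_score`")
  pcs_score < rules$pcs_high_max
}

#' Classify sleep condition
#'
#' Poor sleep is sleeping fewer than `sleep_hours_min` hours (default 7)
#' and/or rating sleep quality in the worst two levels ("fairly bad",
#' "very bad").
#'
#' @param sleep_hours Usual nightly sleep duration in hours (>= 0).
#' @param sleep_quality Character or factor on [sleep_quality_levels()].
#' @inheritParams classify_psychological_distress
#' @return Logical vector: `TRUE` = poor sleep condition.
#' @export
#' @examples
#' classify_sleep(c(6.5, 8, 7), c("very good", "fairly bad", "good"))
classify_sleep <- function(sleep_hours, sleep_quality, rules = risk_rules()) {
  check_nonneg(sleep_hours, "`sleep_hours`")
  q <- check_levels(sleep_quality, sleep_quality_levels(), "`sleep_quality`")
  bad_quality <- q %in% c("fairly bad", "very bad")
  bad_quality[is.na(q)] <- NA
  sleep_hours < rules$sleep_hours_min | bad_quality
}

#' Classify risky alcohol use from the AUDIT-C score
#'
#' Sex-specific cut-offs: AUDIT-C of `auditc_high_min_male` (default 4) or
#' more for men, `auditc_high_min_female` (default 3) or more for women.
#'
#' @param auditc_score Integer AUDIT-C total in 0-12.
#' @param gender Character or factor, `"male"` or `"female"`.
#' @inheritParams classify_psychological_distress
#' @return Logical vector: `TRUE` = risky alcohol use.
#' @export
#' @examples
#' classify_alcohol(c(4, 3, 3), c("male", "male", "female"))
classify_alcohol <- function(auditc_score, gender, rules = risk_rules()) {
  check_range(auditc_score, 0, 12, "`auditc_score`")
  g <- check_levels(gender, c("male", "female"), "`gender`")
  threshold <- ifelse(g == "male",
                      rules$auditc_high_min_male,
                      rules$auditc_high_min_female)
  auditc_score >= threshold
}

#' Classify smoking status
#'
#' Current smokers are high risk; never- and ex-smokers are low risk.
#'
#' @param smoking_status Character or factor on [smoking_levels()].
#' @return Logical vector: `TRUE` = currently smoking.
#' @export
classify_smoking <- function(smoking_status) {
  s <- check_levels(smoking_status, smoking_levels(), "`smoking_status`")
  out <- s == "current"
  out[is.na(s)] <- NA
  out
}

#' IPAQ weekly MET-minutes
#'
#' Converts IPAQ short-form activity reports into total metabolic-equivalent
#' minutes per week: the sum over activities of MET weight x days/week x
#' minutes/day, with the standard weights walking 3.3, moderate 4.0,
#' vigorous 8.0.
#'
#' @param intensity Character vector of `"walking"`, `"moderate"`,
#'   `"vigorous"` (one element per reported activity).
#' @param days_per_week Days per week (0-7) for each activity.
#' @param minutes_per_day Minutes per day (>= 0) for each activity.
#' @return Total MET-minutes per week (length-1 numeric). Call once per
#'   worker, e.g. grouped by worker id.
#' @export
#' @examples
#' ipaq_met_minutes("moderate", 5, 30)                   # 600
#' ipaq_met_minutes(c("walking", "vigorous"), c(7, 2), c(10, 20))  # 551
ipaq_met_minutes <- function(intensity, days_per_week, minutes_per_day) {
  weights <- c(walking = 3.3, moderate = 4.0, vigorous = 8.0)
  if (length(intensity) == 0) return(0)
  i <- check_levels(intensity, names(weights), "`intensity`")
  check_range(days_per_week, 0, 7, "`days_per_week`")
  check_nonneg(minutes_per_day, "`minutes_per_day`")
  sum(weights[i] * days_per_week * minutes_per_day)
}

#' Classify physical activity sufficiency
#'
#' Insufficient physical activity is fewer than `met_min_per_week` (default
#' 600) MET-minutes per week.
#'
#' @param met_minutes Weekly MET-minutes (>= 0), e.g. from
#'   [ipaq_met_minutes()].
#' @inheritParams classify_psychological_distress
#' @return Logical vector: `TRUE` = insufficient activity.
#' @export
classify_physical_activity <- function(met_minutes, rules = risk_rules()) {
  check_nonneg(met_minutes, "`met_minutes`")
  met_minutes < rules$met_min_per_week
}

#' Body mass index
#'
#' @param weight_kg Body weight in kilograms (> 0).
#' @param height_m Height in metres (> 0).
#' @return BMI in kg/m^2.
#' @export
#' @examples
#' bmi(80, 1.79)  # 24.97
bmi <- function(weight_kg, height_m) {
  if (any(!is.na(weight_kg) & weight_kg <= 0) ||
      any(!is.na(height_m) & height_m <= 0)) {
    abort("`weight_kg` and `height_m` must be positive")
  }
  weight_kg / height_m^2
}

#' Classify weight problem from BMI
#'
#' High risk (weight problem) is a BMI below `bmi_low` (underweight,
#' default < 18.5) or at/above `bmi_normal_max` (overweight/obese, default
#' >= 25); the healthy band `[18.5, 25)` is low risk.
#'
#' @param bmi_value BMI in kg/m^2, e.g. from [bmi()].
#' @inheritParams classify_psychological_distress
#' @return Logical vector: `TRUE` = weight problem.
#' @export
classify_weight <- function(bmi_value, rules = risk_rules()) {
  check_nonneg(bmi_value, "`bmi_value`")
  bmi_value < rules$bmi_low | bmi_value >= rules$bmi_normal_max
}

#' Classify diet from fruit and vegetable intake
#'
#' Poor diet is fewer than `fruit_min` (default 2) daily serves of fruit
#' and/or fewer than `veg_min` (default 5) serves of vegetables.
#'
#' @param fruit_serves,veg_serves Daily serves (>= 0).
#' @inheritParams classify_psychological_distress
#' @return Logical vector: `TRUE` = poor diet.
#' @export
classify_diet <- function(fruit_serves, veg_serves, rules = risk_rules()) {
  check_nonneg(fruit_serves, "`fruit_serves`")
  check_nonneg(veg_serves, "`veg_serves`")
  fruit_serves < rules$fruit_min | veg_serves < rules$veg_min
}
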