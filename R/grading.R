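# Echocardiographic diastolic-dysfunction grading by the ASE-recommended
# three-criterion rule, with LV hypertrophy as a modifier.

#' LV hypertrophy from the LV mass index
#'
#' Hypertrophy is an LV mass index strictly above 115 g/m^2 in men or
#' 95 g/m^2 in women (values exactly at the cutoff are not hypertrophy).
#'
#' @param lvmi LV mass index, g/m^2 (vectorised).
#' @param sex `"male"`/`"female"` (`"m"`/`"f"` accepted), vectorised.
#' @param thresholds Named list with `lvmi_male_g_m2`, `lvmi_female_g_m2`
#'   (defaults from [analysis_config()]).
#' @return Logical vector.
#' @examples
#' lv_hypertrophy(c(115, 115.1, 96), c("male", "male", "female"))
#' @export
lv_hypertrophy <- function(lvmi, sex,
                           thresholds = analysis_config()$thresholds) {
  if (any(!is.na(lvmi) & lvmi <= 0)) {
    abort("`lvmi` must be positive.", class = "lvd_error_argument")
  }
  s <- tolower(as.character(sex))
  s[s %in% c("m", "male")] <- "male"
  s[s %in% c("f", "female")] <- "female"
  bad <- !is.na(s) & !s %in% c("male", "female")
  if (any(bad)) {
    abort(sprintf("Unknown sex label(s): %s.",
                  paste(unique(s[bad]), collapse = ", ")),
          class = "lvd_error_argument")
  }
  cutoff <- ifelse(s == "male", thresholds$lvmi_male_g_m2,
                   thresholds$lvmi_female_g_m2)
  lvmi > cutoff
}

#' ASE grading criteria from echocardiographic measures
#'
#' Evaluates the three tissue-Doppler criteria used to grade diastolic
#' dysfunction: septal e' < 8 cm/s, lateral e' < 10 cm/s, and mean E/e'
#' >= 10 (all thresholds strict as written). The mean E/e' is, by default,
#' the mitral E velocity divided by the mean of the septal and lateral e'
#' ("average E over average e'"); `mean_of_ratios` is available as an
#' alternative.
#'
#' @param data Data frame with columns `echo_e_cm_s`, `echo_eprime_septal`,
#'   `echo_eprime_lateral` (cm/s) and, for the hypertrophy flag, `lvmi` and
#'   `sex` (or a logical `lvh` column).
#' @param config An [analysis_config()] (thresholds and E/e' averaging mode).
#' @return The input with logical columns `septal_low`, `lateral_low`,
#'   `ratio_high`, `lvh` and the numeric `echo_eprime_mean`, `echo_ee_mean`
#'   appended.
#' @export
ase_criteria <- function(data, config = analysis_config()) {
  data <- tibble::as_tibble(data)
  need <- c("echo_e_cm_s", "echo_eprime_septal", "echo_eprime_lateral")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Incomplete echo measures: missing %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "lvd_error_incomplete_measures")
  }
  if (anyNA(data[need])) {
    abort("Incomplete echo measures: the three grading fields must be present for every subject.",
          class = "lvd_error_incomplete_measures")
  }
  th <- config$thresholds
  out <- dplyr::mutate(
    data,
    echo_eprime_mean = (.data$echo_eprime_septal + .data$echo_eprime_lateral) / 2,
    echo_ee_mean = if (config$echo_ratio_mode == "ratio_of_means") {
      .data$echo_e_cm_s / .data$echo_eprime_mean
    } else {
      (.data$echo_e_cm_s / .data$echo_eprime_septal +
         .data$echo_e_cm_s / .data$echo_eprime_lateral) / 2
    },
    septal_low = .data$echo_eprime_septal < th$eprime_septal_cm_s,
    lateral_low = .data$echo_eprime_lateral < th$eprime_lateral_cm_s,
    ratio_high = .data$echo_ee_mean >= th$ee_mean
  )
  if (!"lvh" %in% names(out)) {
    if (all(c("lvmi", "sex") %in% names(out))) {
      out$lvh <- lv_hypertrophy(out$lvmi, out$sex, th)
    } else {
      out$lvh <- FALSE
    }
  }
  out
}

#' Diastolic function grade from the ASE criteria
#'
#' All three criteria present: type II (reduced). Exactly two criteria, or
#' exactly one criterion plus LV hypertrophy: type I (impaired). Otherwise
#' normal. Hypertrophy never promotes beyond type I: type II is reserved
#' for the full three-criterion pattern.
#'
#' @param criteria Data frame with logical columns `septal_low`,
#'   `lateral_low`, `ratio_high`, `lvh` (as produced by [ase_criteria()]).
#' @return The input with a `grade` factor column
#'   (`normal` / `type I` / `type II`) and the criterion count `n_criteria`.
#' @export
grade_diastolic_function <- function(criteria) {
  criteria <- tibble::as_tibble(criteria)
  need <- c("septal_low", "lateral_low", "ratio_high", "lvh")
  if (!all(need %in% names(criteria))) {
    abort("`criteria` must have columns septal_low, lateral_low, ratio_high, lvh.",
          class = "lvd_error_schema")
  }
  n_crit <- rowSums(criteria[, c("septal_low", "lateral_low", "ratio_high")])
  grade <- dplyr::case_when(
    n_crit == 3 ~ "type II",
    n_crit == 2 ~ "type I",
    n_crit == 1 & criteria$lvh ~ "type I",
    .default = "normal"
  )
  dplyr::mutate(criteria,
                n_criteria = n_crit,
                grade = factor(grade, levels = grade_levels()))
}

#' Grade an echo cohort in one call
#'
#' Convenience wrapper: [ase_criteria()] followed by
#' [grade_diastolic_function()].
#'
#' @inheritParams ase_criteria
#' @return The graded tibble.
#' @export
grade_cohort <- function(data, config = analysis_config()) {
  grade_diastolic_function(ase_criteria(data, config))
}

#' Ordered diastolic-function grade labels
#' @return `c("normal", "type I", "type II")`.
#' @export
grade_levels <- function() c("normal", "type I", "type II")

#' Apply the heart-rate-variability exclusion rule
#'
#' Subjects whose heart rate differs by more than 15 beats/min between the
#' echocardiographic and CMR studies are flagged for exclusion (the two
#' modalities no longer sample comparable physiology). Nothing is dropped
#' silently: the function partitions the cohort and reports.
#'
#' @param data Cohort tibble with `hr_echo` and `hr_cmr` (beats/min).
#' @param max_diff Exclusion threshold, beats/min (default 15; subjects are
#'   excluded when the absolute difference exceeds it).
#' @return List with `included`, `excluded` (with an `exclusion_reason`
#'   column) and `n_excluded`.
#' @export
apply_hr_exclusion <- function(data, max_diff = 15) {
  data <- tibble::as_tibble(data)
  if (!all(c("hr_echo", "hr_cmr") %in% names(data))) {
    abort("`data` must have columns `hr_echo` and `hr_cmr`.",
          class = "lvd_error_schema")
  }
  if (nrow(data) == 0) {
    return(list(included = data, excluded = data, n_excluded = 0L))
  }
  he <- as.numeric(data$hr_echo)
  hc <- as.numeric(data$hr_cmr)
  bad <- !is.na(he) & !is.na(hc) & abs(he - hc) > max_diff
  excluded <- data[bad, , drop = FALSE]
  if (nrow(excluded) > 0) {
    excluded$exclusion_reason <- sprintf(
      "heart-rate difference %.1f beats/min exceeds %g",
      abs(he[bad] - hc[bad]), max_diff
    )
    inform(sprintf("%d subject(s) excluded for heart-rate variability > %g beats/min.",
                   nrow(excluded), max_diff))
  }
  list(included = data[!bad, , drop = FALSE], excluded = excluded,
       n_excluded = nrow(excluded))
}
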