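# File formats and the end-to-end pipeline: curve/track/subject CSV I/O,
# the cohort-level statistics report, and JSON serialisation.

#' Read / write a volume-curve CSV
#'
#' One file per subject per cycle, columns `time_ms,volume_ml`, header
#' required. The R-R interval travels in the call (curve files carry only
#' the sampled cycle).
#'
#' @param path CSV path.
#' @param rr_interval Cycle length, ms.
#' @param curve A [volume_curve()].
#' @return `read_volume_curve()` a [volume_curve()]; `write_volume_curve()`
#'   the path, invisibly.
#' @export
read_volume_curve <- function(path, rr_interval) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  volume_curve(df, rr_interval = rr_interval)
}

#' @rdname read_volume_curve
#' @export
write_volume_curve <- function(curve, path) {
  stopifnot(inherits(curve, "volume_curve"))
  readr::write_csv(tibble::as_tibble(curve), path)
  invisible(path)
}

#' Read an annulus track CSV
#'
#' Accepts either the distance format `time_ms,distance_mm,site` or the
#' guide-point format `time_ms,x_mm,y_mm,z_mm,label` with labels `apex`,
#' `septal`, `lateral` (distances are then computed per site).
#'
#' @param path CSV path.
#' @param rr_interval Cycle length, ms.
#' @return A named list of [annulus_track()]s (by site).
#' @export
read_annulus_tracks <- function(path, rr_interval) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (all(c("time_ms", "distance_mm", "site") %in% names(df))) {
    sites <- split(df, df$site)
    return(purrr::imap(sites, function(d, s) {
      annulus_track(d[, c("time_ms", "distance_mm")], site = s,
                    rr_interval = rr_interval)
    }))
  }
  if (all(c("time_ms", "x_mm", "y_mm", "z_mm", "label") %in% names(df))) {
    pts <- split(df, df$label)
    if (!"apex" %in% names(pts)) {
      abort("Guide-point file must contain an `apex` label.",
            class = "lvd_error_schema")
    }
    apex <- pts$apex[order(pts$apex$time_ms), c("x_mm", "y_mm", "z_mm")]
    out <- list()
    for (s in intersect(c("septal", "lateral"), names(pts))) {
      ann <- pts[[s]][order(pts[[s]]$time_ms), ]
      out[[s]] <- apex_annulus_distance_series(
        apex, ann[, c("x_mm", "y_mm", "z_mm")], times = ann$time_ms,
        site = s, rr_interval = rr_interval
      )
    }
    return(out)
  }
  abort("Unrecognised track schema: need time_ms,distance_mm,site or time_ms,x_mm,y_mm,z_mm,label.",
        class = "lvd_error_schema")
}

#' Read a subject table with row-level validation
#'
#' One row per subject; column names follow the package's cohort schema
#' (see [simulate_cohort()]). Rows violating the 15 beats/min heart-rate
#' agreement rule between the two same-day studies are flagged as excluded,
#' not silently dropped; other row-level problems are collected and
#' reported.
#'
#' @param path CSV path.
#' @param max_hr_diff Exclusion threshold, beats/min.
#' @return List with `subjects` (validated tibble), `excluded` and
#'   `problems` (tibble of row-level issues).
#' @export
read_subject_table <- function(path, max_hr_diff = 15) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"id" %in% names(df)) {
    abort("Subject table must have an `id` column.", class = "lvd_error_schema")
  }
  problems <- tibble::tibble(id = character(0), issue = character(0))
  num_cols <- setdiff(names(df)[vapply(df, is.numeric, logical(1))], "id")
  for (cl in intersect(num_cols, c("echo_e_cm_s", "echo_a_cm_s",
                                   "echo_eprime_septal", "echo_eprime_lateral",
                                   "cmr_e_ml_s", "cmr_edv_ml", "lvmi"))) {
    bad <- which(!is.na(df[[cl]]) & df[[cl]] <= 0)
    if (length(bad) > 0) {
      problems <- dplyr::bind_rows(problems, tibble::tibble(
        id = as.character(df$id[bad]),
        issue = sprintf("non-positive %s", cl)
      ))
    }
  }
  if (all(c("hr_echo", "hr_cmr") %in% names(df))) {
    split_hr <- apply_hr_exclusion(df, max_diff = max_hr_diff)
  } else {
    split_hr <- list(included = df,
                     excluded = df[0, , drop = FALSE], n_excluded = 0L)
  }
  list(subjects = tibble::as_tibble(split_hr$included),
       excluded = tibble::as_tibble(split_hr$excluded),
       problems = problems)
}

#' @rdname read_subject_table
#' @param subjects Cohort tibble.
#' @param path Output CSV path.
#' @export
write_subject_table <- function(subjects, path) {
  readr::write_csv(tibble::as_tibble(subjects), path)
  invisible(path)
}

# Continuous variables summarised per grade in the characteristics table,
# and the echo-vs-CMR pairs of the correlation table.
report_continuous_vars <- function() c(
  "age", "lv_mass_g", "bsa_m2", "lvmi", "hr_echo", "hr_cmr",
  "echo_e_cm_s", "echo_dt_ms", "echo_a_cm_s", "echo_ea",
  "echo_eprime_septal", "echo_eprime_lateral", "echo_eprime_mean",
  "echo_ee_septal", "echo_ee_lateral", "echo_ee_mean",
  "cmr_e_ml_s", "cmr_ne", "cmr_dt_ms", "cmr_tpe_ms", "cmr_a_ml_s",
  "cmr_na", "cmr_tpa_ms", "cmr_ea", "cmr_dvr_ms", "cmr_edv_ml",
  "cmr_eprime_septal", "cmr_eprime_lateral", "cmr_eprime_mean",
  "cmr_ee_septal", "cmr_ee_lateral", "cmr_ee_mean"
)

report_correlation_pairs <- function() tibble::tribble(
  ~echo, ~cmr,
  "echo_e_cm_s", "cmr_e_ml_s",
  "echo_e_cm_s", "cmr_ne",
  "echo_a_cm_s", "cmr_a_ml_s",
  "echo_a_cm_s", "cmr_na",
  "echo_ea", "cmr_ea",
  "echo_eprime_septal", "cmr_eprime_septal",
  "echo_ee_septal", "cmr_ee_septal",
  "echo_eprime_lateral", "cmr_eprime_lateral",
  "echo_ee_lateral", "cmr_ee_lateral",
  "echo_eprime_mean", "cmr_eprime_mean",
  "echo_ee_mean", "cmr_ee_mean"
)

report_roc_vars <- function() tibble::tribble(
  ~variable, ~direction,
  "cmr_e_ml_s", "higher",
  "cmr_ne", "higher",
  "cmr_dt_ms", "higher",
  "cmr_a_ml_s", "higher",
  "cmr_na", "higher",
  "cmr_dvr_ms", "higher",
  "cmr_ea", "higher",
  "cmr_eprime_septal", "lower",
  "cmr_ee_septal", "higher",
  "cmr_eprime_lateral", "lower",
  "cmr_ee_lateral", "higher",
  "cmr_eprime_mean", "lower",
  "cmr_ee_mean", "higher"
)

#' Cohort-level validation report
#'
#' Runs the full statistical battery over a graded cohort: per-grade
#' descriptives with omnibus one-way ANOVA p-values for continuous
#' variables and exact contingency tests for categorical ones; echo-vs-CMR
#' Pearson correlations; ROC analyses of every CMR index against the
#' echo-defined reduced-vs-normal contrast (type I subjects excluded);
#' Bland-Altman for the one shared-unit pair (E/A); and paired comparisons
#' of the diastolic time intervals and cycle length across modalities.
#' Component failures (e.g. a single-grade cohort making ROC degenerate)
#' are collected in `$errors` rather than aborting the run.
#'
#' @param subjects Graded cohort tibble (a `grade` factor column plus any
#'   subset of the standard measure columns).
#' @param config An [analysis_config()].
#' @return An object of class `cohort_report`.
#' @export
cohort_report <- function(subjects, config = analysis_config()) {
  subjects <- tibble::as_tibble(subjects)
  if (!"grade" %in% names(subjects)) {
    abort("`subjects` must carry a `grade` column; see grade_cohort().",
          class = "lvd_error_schema")
  }
  grade <- factor(subjects$grade, levels = grade_levels())
  errors <- tibble::tibble(stage = character(0), message = character(0))
  note <- function(stage, e) {
    errors <<- dplyr::bind_rows(errors,
                                tibble::tibble(stage = stage,
                                               message = conditionMessage(e)))
    NULL
  }

  characteristics <- purrr::map_dfr(
    intersect(report_continuous_vars(), names(subjects)),
    function(v) {
      res <- tryCatch(
        anova_oneway(dplyr::tibble(value = subjects[[v]], grade = grade),
                     value, grade),
        error = function(e) note(paste0("anova:", v), e)
      )
      sm <- dplyr::summarise(
        dplyr::group_by(tibble::tibble(value = subjects[[v]], grade = grade),
                        grade),
        n = sum(!is.na(.data$value)),
        mean = mean(.data$value, na.rm = TRUE),
        sd = sd(.data$value, na.rm = TRUE), .groups = "drop"
      )
      tibble::tibble(
        variable = v,
        summary = paste(sprintf("%s: %.2f +/- %.2f (n=%d)", sm$grade,
                                sm$mean, sm$sd, sm$n), collapse = "; "),
        p.value = if (is.null(res)) NA_real_ else res$p.value
      )
    }
  )

  categorical <- purrr::map_dfr(
    intersect(c("sex", "hypertension", "diabetes"), names(subjects)),
    function(v) {
      tb <- table(subjects[[v]], grade)
      res <- tryCatch(
        fisher_exact_rxc(tb, enum_limit = config$fisher_enum_limit,
                         mc_draws = config$mc_draws, seed = config$seed),
        error = function(e) note(paste0("fisher:", v), e)
      )
      tibble::tibble(
        variable = v,
        summary = paste(apply(tb, 1, paste, collapse = "/"), collapse = " vs "),
        p.value = if (is.null(res)) NA_real_ else res$p.value
      )
    }
  )

  pairs <- report_correlation_pairs()
  pairs <- pairs[pairs$echo %in% names(subjects) & pairs$cmr %in% names(subjects), ]
  correlations <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    res <- tryCatch(
      pearson_linear(subjects, !!rlang::sym(pairs$echo[i]),
                     !!rlang::sym(pairs$cmr[i])),
      error = function(e) note(paste0("pearson:", pairs$echo[i]), e)
    )
    if (is.null(res)) return(NULL)
    dplyr::bind_cols(tibble::tibble(echo = pairs$echo[i], cmr = pairs$cmr[i]), res)
  })

  keep <- grade %in% c("normal", "type II")
  rocs <- report_roc_vars()
  rocs <- rocs[rocs$variable %in% names(subjects), ]
  roc <- purrr::map_dfr(seq_len(nrow(rocs)), function(i) {
    res <- tryCatch(
      roc_auc_with_band(subjects[[rocs$variable[i]]][keep],
                        grade[keep] == "type II",
                        direction = rocs$direction[i]),
      error = function(e) note(paste0("roc:", rocs$variable[i]), e)
    )
    if (is.null(res)) return(NULL)
    dplyr::bind_cols(tibble::tibble(variable = rocs$variable[i],
                                    direction = rocs$direction[i]), tidy(res))
  })

  agreement <- NULL
  if (all(c("echo_ea", "cmr_ea") %in% names(subjects))) {
    agreement <- tryCatch(bland_altman(subjects$echo_ea, subjects$cmr_ea),
                          error = function(e) note("bland_altman:ea", e))
  }

  modality <- purrr::map_dfr(
    list(c("echo_tpe_ms", "cmr_tpe_ms"), c("echo_tpa_ms", "cmr_tpa_ms"),
         c("rr_echo_ms", "rr_cmr_ms")),
    function(pp) {
      if (!all(pp %in% names(subjects))) return(NULL)
      res <- tryCatch(paired_mean_comparison(subjects[[pp[1]]], subjects[[pp[2]]]),
                      error = function(e) note(paste0("paired:", pp[1]), e))
      if (is.null(res)) return(NULL)
      dplyr::bind_cols(tibble::tibble(echo = pp[1], cmr = pp[2],
                                      mean_echo = mean(subjects[[pp[1]]], na.rm = TRUE),
                                      mean_cmr = mean(subjects[[pp[2]]], na.rm = TRUE)),
                       res)
    }
  )

  structure(
    list(subjects = subjects,
         characteristics = dplyr::bind_rows(characteristics, categorical),
         correlations = correlations, roc = roc, agreement = agreement,
         modality = modality, errors = errors, config = config),
    class = "cohort_report"
  )
}

#' @exportS3Method generics::glance
glance.cohort_report <- function(x, ...) {
  counts <- table(factor(x$subjects$grade, levels = grade_levels()))
  tibble::tibble(
    n = nrow(x$subjects),
    n_normal = unname(counts["normal"]),
    n_type_i = unname(counts["type I"]),
    n_type_ii = unname(counts["type II"]),
    n_errors = nrow(x$errors)
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Cohort report: %d subjects (normal %d / type I %d / type II %d)\n",
              g$n, g$n_normal, g$n_type_i, g$n_type_ii))
  cat(sprintf("  %d characteristic rows, %d correlations, %d ROC rows, %d stage errors\n",
              nrow(x$characteristics), nrow(x$correlations), nrow(x$roc),
              nrow(x$errors)))
  if (nrow(x$errors) > 0) {
    cat("  stages with errors:", paste(x$errors$stage, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run the full pipeline over a cohort
#'
#' End to end: heart-rate exclusion, optional per-subject curve/track
#' analysis (filling the `cmr_*` columns from raw curves), echo-based
#' grading, and the cohort-level statistics report. Per-subject analysis
#' failures are recorded with the subject id and stage; they do not abort
#' the run.
#'
#' @param subjects Cohort tibble (echo measures and covariates; `cmr_*`
#'   columns optional when curves are supplied).
#' @param curves Optional named list of [volume_curve()]s keyed by subject
#'   id.
#' @param tracks Optional named list (by id) of lists with elements `septal`
#'   and/or `lateral` ([annulus_track()]s).
#' @param config An [analysis_config()].
#' @return A `cohort_report` whose `$subjects` carries grades (and analysed
#'   indices when curves were given).
#' @export
run_pipeline <- function(subjects, curves = NULL, tracks = NULL,
                         config = analysis_config()) {
  subjects <- tibble::as_tibble(subjects)
  excl <- if (all(c("hr_echo", "hr_cmr") %in% names(subjects))) {
    apply_hr_exclusion(subjects)
  } else {
    list(included = subjects, excluded = subjects[0, ], n_excluded = 0L)
  }
  subjects <- excl$included
  subject_errors <- tibble::tibble(id = character(0), message = character(0))

  if (!is.null(curves)) {
    index_map <- c(
      cmr_e_ml_s = "e_ml_s", cmr_a_ml_s = "a_ml_s", cmr_ne = "ne_per_s",
      cmr_na = "na_per_s", cmr_ea = "ea", cmr_dt_ms = "dt_ms",
      cmr_dvr_ms = "dvr_ms", cmr_edv_ml = "edv_ml",
      cmr_eprime_septal = "eprime_septal_mm_s",
      cmr_eprime_lateral = "eprime_lateral_mm_s",
      cmr_eprime_mean = "eprime_mean_mm_s",
      cmr_ee_septal = "ee_septal_ml_mm", cmr_ee_lateral = "ee_lateral_ml_mm",
      cmr_ee_mean = "ee_mean_ml_mm"
    )
    for (i in seq_len(nrow(subjects))) {
      id <- as.character(subjects$id[i])
      if (is.null(curves[[id]])) next
      trk <- tracks[[id]]
      fit <- tryCatch(
        suppressWarnings(
          analyze_curve(curves[[id]], septal = trk$septal,
                        lateral = trk$lateral, config = config)
        ),
        error = function(e) {
          subject_errors <<- dplyr::bind_rows(
            subject_errors,
            tibble::tibble(id = id, message = conditionMessage(e))
          )
          NULL
        }
      )
      if (is.null(fit)) next
      ind <- fit$indices
      for (cl in names(index_map)) {
        subjects[i, cl] <- ind[[index_map[[cl]]]]
      }
    }
  }

  graded <- grade_cohort(subjects, config)
  report <- cohort_report(graded, config)
  report$excluded <- excl$excluded
  report$subject_errors <- subject_errors
  report
}

#' Serialise a cohort report to JSON
#'
#' Machine-readable mirror of the report tables (characteristics,
#' correlations, ROC, agreement, modality comparison, grade counts), with
#' p-values both raw and in display format.
#'
#' @param report A `cohort_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "cohort_report"))
  fmt <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(df)
    if ("p.value" %in% names(df)) df$p_display <- format_p(df$p.value)
    df
  }
  payload <- list(
    n = nrow(report$subjects),
    grades = as.list(table(factor(report$subjects$grade,
                                  levels = grade_levels()))),
    characteristics = fmt(report$characteristics),
    correlations = fmt(report$correlations),
    roc = fmt(report$roc),
    agreement = if (!is.null(report$agreement)) tidy(report$agreement),
    modality_comparison = fmt(report$modality),
    errors = report$errors
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}
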