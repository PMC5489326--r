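# Mitral-annulus kinematics: apex-to-annulus distance tracks and the early
# longitudinal relaxation rate E'.

#' Construct a validated apex-annulus distance track
#'
#' One cardiac cycle of the distance (mm) between a mitral-annulus guide
#' point (septal or lateral junction of the LV wall with the annulus) and
#' the ventricular apex, on the same trigger-locked grid as the volume
#' curve. During early diastole the annulus moves away from the apex as the
#' ventricle lengthens; the maximal rate of that lengthening is E'.
#'
#' @param data Data frame with columns `time_ms` and `distance_mm`.
#' @param site `"septal"` or `"lateral"`.
#' @param rr_interval Cycle length, ms.
#' @return A tibble of class `annulus_track` with attributes `site` and
#'   `rr_interval`.
#' @export
annulus_track <- function(data, site = c("septal", "lateral"), rr_interval) {
  site <- match.arg(site)
  data <- tibble::as_tibble(data)
  if (!all(c("time_ms", "distance_mm") %in% names(data))) {
    abort("`data` must have columns `time_ms` and `distance_mm`.",
          class = "lvd_error_schema")
  }
  t <- as.numeric(data$time_ms)
  d <- as.numeric(data$distance_mm)
  if (length(t) != length(d) || anyNA(t) || anyNA(d)) {
    abort("Track samples must be complete.", class = "lvd_error_invariant")
  }
  if (any(diff(t) <= 0) || t[1] != 0 || t[length(t)] >= rr_interval) {
    abort("Track times must be strictly increasing, start at 0, and end inside the R-R interval.",
          class = "lvd_error_invariant")
  }
  if (any(d <= 0)) {
    abort("Apex-annulus distances must be positive.", class = "lvd_error_invariant")
  }
  out <- tibble::tibble(time_ms = t, distance_mm = d)
  attr(out, "rr_interval") <- as.numeric(rr_interval)
  attr(out, "site") <- site
  class(out) <- c("annulus_track", class(out))
  out
}

#' Apex-annulus distance series from 3D guide points
#'
#' Per-frame Euclidean distance between the model apex and an annular guide
#' point, both given as 3D coordinates in mm.
#'
#' @param apex,annulus Data frames or matrices with columns `x_mm`, `y_mm`,
#'   `z_mm` (or three unnamed columns), one row per frame.
#' @param times Frame times, ms.
#' @param site `"septal"` or `"lateral"`.
#' @param rr_interval Cycle length, ms.
#' @return An [annulus_track()].
#' @export
apex_annulus_distance_series <- function(apex, annulus, times,
                                         site = c("septal", "lateral"),
                                         rr_interval) {
  site <- match.arg(site)
  apex <- as.matrix(as.data.frame(apex))
  annulus <- as.matrix(as.data.frame(annulus))
  if (nrow(apex) != nrow(annulus) || nrow(apex) != length(times)) {
    abort("Apex and annulus tracks must have one 3D point per frame.",
          class = "lvd_error_structure")
  }
  if (ncol(apex) != 3 || ncol(annulus) != 3) {
    abort("Guide points must have exactly three coordinates (mm).",
          class = "lvd_error_structure")
  }
  d <- sqrt(rowSums((annulus - apex)^2))
  annulus_track(tibble::tibble(time_ms = times, distance_mm = d),
                site = site, rr_interval = rr_interval)
}

#' Early longitudinal relaxation rate E'
#'
#' E' is the maximum positive rate of change of the apex-annulus distance
#' within the early-diastolic window `(es_time, window_end]`, in mm/s. The
#' derivative uses the same cyclic central-difference scheme as the volume
#' curves; the sampled maximum is optionally refined with a 3-point
#' parabola.
#'
#' @param track An [annulus_track()].
#' @param es_time End-systolic time, ms.
#' @param window_end End of the early-diastolic window, ms. Callers
#'   typically use `es + 0.6 * (rr - es)`, shortened to the A-lobe onset
#'   when one was detected (see [analysis_config()]).
#' @param refine Refine the sampled maximum off-grid (default `TRUE`): the
#'   spectral derivative of the trigonometric interpolant is searched within
#'   one frame of the sampled maximum (inside the window).
#' @return E' in mm/s.
#' @export
early_relaxation_rate <- function(track, es_time, window_end, refine = TRUE) {
  stopifnot(inherits(track, "annulus_track"))
  t <- track$time_ms
  rr <- rr_interval(track)
  vel <- central_diff_cyclic(t, track$distance_mm, rr) * 1000 # mm/s
  win <- which(t > es_time & t <= window_end)
  if (length(win) < 3) {
    abort("The early-diastolic window must contain at least 3 samples.",
          class = "lvd_error_insufficient_samples")
  }
  if (all(vel[win] <= 0)) {
    abort("No annular lengthening in the early-diastolic window (no-relaxation).",
          class = "lvd_error_no_relaxation")
  }
  i <- win[which.max(vel[win])]
  if (!isTRUE(refine)) return(vel[i])
  h <- stats::median(diff(t))
  # jittery tracks get the robust 3-point parabola; clean tracks the dense
  # spectral refinement (same policy as the volume-curve analysis)
  sigma_d <- signal_noise_sigma(track$distance_mm)
  if (sigma_d * sqrt(2) / (2 * h) * 1000 > 0.004 * max(abs(vel))) {
    if (i > 1 && i < length(t)) {
      return(parabolic_refine(t[(i - 1):(i + 1)], vel[(i - 1):(i + 1)])$y)
    }
    return(vel[i])
  }
  n_dense <- length(t) * max(2L, ceiling(h / 2))
  dd <- trig_deriv_dense(t, track$distance_mm, rr, n_dense, damp = TRUE)
  dwin <- which(dd$t >= max(t[i] - h, es_time) &
                  dd$t <= min(t[i] + h, window_end))
  if (length(dwin) == 0) return(vel[i])
  max(dd$d[dwin]) * 1000
}

#' E/E' ratio
#'
#' Ratio of the CMR early peak filling rate (mL/s) to the early longitudinal
#' relaxation rate (mm/s). Unlike its dimensionless echocardiographic
#' counterpart E/e', the CMR ratio carries units of mL/mm.
#'
#' @param e Early peak filling rate, mL/s.
#' @param eprime Early longitudinal relaxation rate, mm/s.
#' @return E/E' in mL/mm.
#' @export
e_over_eprime <- function(e, eprime) {
  if (any(!is.na(eprime) & eprime <= 0)) {
    abort("`eprime` must be positive.", class = "lvd_error_argument")
  }
  e / eprime
}
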