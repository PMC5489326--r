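# Diastolic filling indices from a volume-curve / filling-rate pair:
# E, A, NE, NA, E/A, deceleration time, diastolic volume recovery, and the
# times to peak, plus the analyze_curve() orchestrator.

#' Detect the early (E) filling-rate peak
#'
#' E is the first local maximum of the filling rate after end-systole, in
#' mL/s; RTPE is the time from end-systole to that peak. When the post-ES
#' rate is monotonically decreasing (no interior maximum), the first post-ES
#' sample is taken as E with a warning; a cycle with no positive rate after
#' end-systole raises a no-filling error.
#'
#' @param rate A `filling_rate_curve` from [derive_filling_rate()].
#' @param es_time End-systolic time in ms (see [locate_end_systole()]).
#' @param refine Refine the peak value/time off-grid (default `TRUE`): from
#'   the dense rate when `dense` is given, otherwise with a 3-point parabola
#'   through the sampled maximum.
#' @param dense Optional densely resampled rate (see [dense_filling_rate()])
#'   used for the refinement.
#' @param min_peak Prominence guard: local maxima at or below this rate
#'   (mL/s) are ignored. Default 0; [analyze_curve()] raises it to three
#'   times the estimated rate noise on noisy curves.
#' @return One-row tibble: `e_ml_s`, `time_ms`, `rtpe_ms`, `frame`.
#' @export
detect_e_peak <- function(rate, es_time, refine = TRUE, dense = NULL,
                          min_peak = 0) {
  stopifnot(inherits(rate, "filling_rate_curve"))
  t <- rate$time_ms
  r <- rate$rate_ml_s
  after <- which(t > es_time)
  if (length(after) == 0 || all(r[after] <= 0)) {
    abort("No positive filling rate after end-systole (no-filling cycle).",
          class = "lvd_error_no_filling")
  }
  mx <- local_maxima(r)
  mx <- mx[t[mx] > es_time & r[mx] > max(0, min_peak)]
  if (length(mx) > 0) {
    i <- mx[1]
    pk <- refine_peak(t, r, i, refine, dense, lower = es_time)
  } else {
    pos <- after[r[after] > 0]
    i <- if (all(diff(r[pos]) <= 0)) pos[1] else pos[which.max(r[pos])]
    warn("No interior filling-rate maximum after end-systole; using a boundary sample as E.",
         class = "lvd_warning_boundary_peak")
    pk <- list(t = t[i], y = r[i])
  }
  tibble::tibble(e_ml_s = pk$y, time_ms = pk$t, rtpe_ms = pk$t - es_time,
                 frame = i)
}

#' Detect the atrial (A) filling-rate peak
#'
#' A is the first local maximum of the filling rate strictly after the
#' trough that follows the E peak; RTPA is measured from end-systole.
#' Absence of a second peak (fused E/A filling) is a valid outcome and
#' returns a zero-row tibble.
#'
#' @param rate A `filling_rate_curve`.
#' @param es_time End-systolic time, ms.
#' @param e_time Time of the detected E peak, ms.
#' @param refine Refine the peak off-grid (default `TRUE`).
#' @param dense Optional densely resampled rate for the refinement.
#' @param min_peak Prominence guard, as in [detect_e_peak()].
#' @return Tibble with columns `a_ml_s`, `time_ms`, `rtpa_ms`, `frame`,
#'   `trough_time_ms`; zero rows when no A wave exists.
#' @export
detect_a_peak <- function(rate, es_time, e_time, refine = TRUE, dense = NULL,
                          min_peak = 0) {
  stopifnot(inherits(rate, "filling_rate_curve"))
  t <- rate$time_ms
  r <- rate$rate_ml_s
  absent <- tibble::tibble(a_ml_s = numeric(0), time_ms = numeric(0),
                           rtpa_ms = numeric(0), frame = integer(0),
                           trough_time_ms = numeric(0))
  mn <- local_minima(r)
  mn <- mn[t[mn] > e_time]
  if (length(mn) == 0) return(absent)
  trough <- mn[1]
  mx <- local_maxima(r)
  mx <- mx[t[mx] > t[trough] & r[mx] > max(0, min_peak)]
  if (length(mx) == 0) return(absent)
  i <- mx[1]
  pk <- refine_peak(t, r, i, refine, dense, lower = t[trough])
  tibble::tibble(a_ml_s = pk$y, time_ms = pk$t, rtpa_ms = pk$t - es_time,
                 frame = i, trough_time_ms = t[trough])
}

#' Normalise a peak filling rate by end-diastolic volume
#'
#' NE = E / EDV and NA = A / EDV (units 1/s): the peak filling rate
#' expressed per unit chamber volume, making curves of different heart
#' sizes comparable.
#'
#' @param peak Peak filling rate, mL/s.
#' @param edv End-diastolic volume, mL.
#' @return Normalised rate, 1/s.
#' @examples
#' normalize_peak(189.30, 106.8) # ~1.77 1/s
#' @export
normalize_peak <- function(peak, edv) {
  if (any(!is.na(edv) & edv <= 0)) {
    abort("`edv` must be positive.", class = "lvd_error_argument")
  }
  peak / edv
}

#' E/A ratio
#'
#' Ratio of the early to the atrial peak filling rate. An absent A wave
#' (NA) propagates to an absent ratio.
#'
#' @param e,a Peak rates in the same units; `a` may be `NA` (fused wave).
#' @return `e / a`, with `NA` where `a` is absent.
#' @export
ea_ratio <- function(e, a) {
  if (any(!is.na(a) & a <= 0)) {
    abort("Present `a` values must be positive.", class = "lvd_error_argument")
  }
  ifelse(is.na(a), NA_real_, e / a)
}

#' Deceleration time of the E wave
#'
#' A line is fitted to the descending limb of the E lobe -- the samples from
#' the peak (inclusive) to the first subsequent local minimum (exclusive) --
#' and extrapolated to the zero-rate baseline. DT is the time from the E
#' peak to that zero crossing. The default fit is least squares over the
#' whole downslope; `"chord"` uses the line through its first and last
#' sample.
#'
#' @param rate A `filling_rate_curve`.
#' @param e_peak_time Time of the E peak, ms (possibly off-grid).
#' @param e_frame Sample index of the E-peak frame; located from
#'   `e_peak_time` when omitted.
#' @param method `"least_squares"` (default) or `"chord"`.
#' @return Deceleration time in ms.
#' @export
deceleration_time <- function(rate, e_peak_time, e_frame = NULL,
                              method = c("least_squares", "chord")) {
  stopifnot(inherits(rate, "filling_rate_curve"))
  method <- match.arg(method)
  t <- rate$time_ms
  r <- rate$rate_ml_s
  n <- length(t)
  i <- e_frame %||% which.min(abs(t - e_peak_time))
  j <- i
  while (j < n && r[j + 1] < r[j]) j <- j + 1
  if (j - i + 1 < 2) {
    abort("The E-wave descending limb has fewer than 2 samples.",
          class = "lvd_error_insufficient_samples")
  }
  win <- i:j
  if (method == "least_squares") {
    fit <- lm(r[win] ~ t[win])
    b <- coef(fit)[[2]]
    a <- coef(fit)[[1]]
  } else {
    b <- (r[j] - r[i]) / (t[j] - t[i])
    a <- r[i] - b * t[i]
  }
  if (!is.finite(b) || b >= 0) {
    abort("Non-negative fitted downslope; deceleration time is undefined.",
          class = "lvd_error_degenerate_downslope")
  }
  (-a / b) - e_peak_time
}

#' Diastolic volume recovery time
#'
#' DVR is the time from end-systole until the cavity has refilled to 80% of
#' the stroke volume, i.e. the first upward crossing of ESV + 0.8 * SV after
#' end-systole, with linear interpolation between the bracketing frames.
#'
#' @param curve A [volume_curve()].
#' @param es_time End-systolic time, ms.
#' @param fraction Recovered fraction of stroke volume defining the target
#'   (default 0.8).
#' @param dense Optional dense resampling of the volume (tibble `time_ms`,
#'   `volume_ml` from the trigonometric interpolant); when given, the
#'   crossing is bracketed on the dense grid for sub-frame accuracy.
#' @return DVR in ms.
#' @export
diastolic_volume_recovery <- function(curve, es_time, fraction = 0.8,
                                      dense = NULL) {
  stopifnot(inherits(curve, "volume_curve"))
  t <- curve$time_ms
  v <- curve$volume_ml
  if (!is.null(dense)) {
    t <- dense$time_ms
    v <- dense$volume_ml
  }
  esv <- min(v)
  sv <- max(v) - esv
  if (sv <= 0) abort("Stroke volume must be positive.", class = "lvd_error_argument")
  thr <- esv + fraction * sv
  after <- which(t > es_time)
  hit <- after[v[after] >= thr]
  if (length(hit) == 0) {
    abort(sprintf("Volume never recovers to %.0f%% of stroke volume after end-systole.",
                  100 * fraction),
          class = "lvd_error_no_recovery")
  }
  k <- hit[1]
  if (k == 1 || v[k - 1] >= thr || v[k] == v[k - 1]) {
    t_cross <- t[k]
  } else {
    t_cross <- t[k - 1] + (thr - v[k - 1]) / (v[k] - v[k - 1]) * (t[k] - t[k - 1])
    t_cross <- max(t_cross, es_time)
  }
  t_cross - es_time
}

# Peak refinement shared by the detectors: with a dense rate, take its
# maximum within one coarse frame of the sampled peak (never before
# `lower`); otherwise fit a 3-point parabola through the sampled maximum.
refine_peak <- function(t, r, i, refine, dense, lower) {
  if (!isTRUE(refine)) return(list(t = t[i], y = r[i]))
  if (!is.null(dense)) {
    h <- if (length(t) > 1) stats::median(diff(t)) else Inf
    win <- which(dense$time_ms >= max(t[i] - h, lower) &
                   dense$time_ms <= t[i] + h)
    if (length(win) > 0) {
      j <- win[which.max(dense$rate_ml_s[win])]
      return(list(t = dense$time_ms[j], y = dense$rate_ml_s[j]))
    }
  }
  if (i > 1 && i < length(r)) {
    parabolic_refine(t[(i - 1):(i + 1)], r[(i - 1):(i + 1)])
  } else {
    list(t = t[i], y = r[i])
  }
}

# End-systolic time refinement: the flow crosses zero from ejection to
# filling at end-systole. To be robust to interpolation ripple around the
# zero-flow baseline, the search anchors at the last sample where ejection
# is still substantial (2% of the peak ejection rate) within `window_ms`
# of the minimum-volume frame, then takes the first zero crossing after it.
# Falls back to the sampled frame time when no anchor exists.
refine_es_time <- function(rate, es_frame_time, window_ms) {
  t <- rate$time_ms
  r <- rate$rate_ml_s
  j <- which.min(r) # ejection peak: unambiguous anchor inside systole
  if (r[j] >= 0) return(es_frame_time)
  # fit a quadratic to the decaying ejection tail (2%-30% of the peak
  # magnitude) and extrapolate it to zero; this stays clear of both the
  # interpolation ripple around the baseline and the early-filling upstroke
  k <- j # contiguous tail: stop where ejection falls below 2% of its peak
  n_all <- length(t)
  while (k < n_all && r[k + 1] < 0.02 * r[j]) k <- k + 1
  band <- which(t > t[j] & t <= min(t[k], es_frame_time + window_ms) &
                  r < 0.02 * r[j] & r > 0.30 * r[j])
  if (length(band) >= 4) {
    # a smooth ejection tail vanishes quadratically, so sqrt(-rate) is
    # nearly linear in time; its extrapolated root is the end of ejection
    tt <- t[band]
    fit <- lm(sqrt(-r[band]) ~ tt)
    cf <- coef(fit)
    if (is.finite(cf[2]) && cf[2] < 0) {
      est <- -cf[1] / cf[2]
      if (est >= max(tt) && abs(est - es_frame_time) <= window_ms) {
        return(unname(est))
      }
    }
  }
  # fallback: first zero crossing after the ejection peak
  n <- length(t)
  while (j < n && r[j + 1] < 0) j <- j + 1
  if (j >= n) return(es_frame_time)
  est <- t[j] + (0 - r[j]) / (r[j + 1] - r[j]) * (t[j + 1] - t[j])
  if (abs(est - es_frame_time) > window_ms) es_frame_time else est
}

# Re-raise component errors with the pipeline stage in the message while
# preserving their condition classes.
with_stage <- function(stage, expr) {
  withCallingHandlers(
    tryCatch(expr, error = function(e) {
      abort(paste0("[", stage, "] ", conditionMessage(e)),
            class = setdiff(class(e), c("error", "condition")))
    }),
    warning = function(w) {
      warn(paste0("[", stage, "] ", conditionMessage(w)),
           class = setdiff(class(w), c("warning", "condition", "simpleWarning")))
      invokeRestart("muffleWarning")
    }
  )
}

#' Full diastolic analysis of one cardiac cycle
#'
#' Orchestrates the whole CMR index set from a volume curve and optional
#' septal/lateral apex-annulus distance tracks: filling-rate derivation,
#' end-systole location, E and A peaks (with times), NE/NA, E/A,
#' deceleration time, diastolic volume recovery, E' per annular site and
#' E/E'. An absent A wave leaves all A-derived fields `NA` (fused filling is
#' physiological, not an error).
#'
#' @param curve A [volume_curve()].
#' @param septal,lateral Optional [annulus_track()]s on the same time grid.
#' @param config An [analysis_config()].
#' @return An object of class `diastolic_fit`; [glance()] gives the one-row
#'   index table, [tidy()] a long form, and [autoplot()] a marked volume and
#'   filling-rate plot.
#' @examples
#' sim <- simulate_volume_curve(curve_params(), seed = 1)
#' fit <- analyze_curve(sim$curve)
#' glance(fit)
#' @export
analyze_curve <- function(curve, septal = NULL, lateral = NULL,
                          config = analysis_config()) {
  stopifnot(inherits(curve, "volume_curve"), inherits(config, "lvd_config"))
  rr <- rr_interval(curve)
  edv <- max(curve$volume_ml)
  esv <- min(curve$volume_ml)
  sv <- edv - esv

  rate <- with_stage("derive_filling_rate", derive_filling_rate(curve, smooth = config$smooth))
  dense <- if (config$refine_peaks || config$refine_es) {
    with_stage("dense_filling_rate", dense_filling_rate(curve))
  }
  h <- temporal_resolution(rr, nrow(curve))
  # estimated volume noise decides how aggressively to refine: sub-frame
  # spectral refinement helps exact curves but chases noise spikes on noisy
  # ones, where the sampled grid plus parabolic refinement is the robust
  # choice
  sigma_v <- signal_noise_sigma(curve$volume_ml)
  sigma_r <- sigma_v * sqrt(2) / (2 * h) * 1000
  noisy <- sigma_r > 0.004 * max(abs(rate$rate_ml_s))
  dense_refine <- if (noisy) NULL else dense
  min_peak <- if (noisy) 3 * sigma_r else 0

  es <- locate_end_systole(curve)
  es_time <- if (config$refine_es && !is.null(dense)) {
    refine_es_time(dense, es$time_ms, window_ms = 1.7 * h)
  } else {
    es$time_ms
  }

  e <- with_stage("detect_e_peak",
                  detect_e_peak(rate, es_time, refine = config$refine_peaks,
                                dense = dense_refine, min_peak = min_peak))
  a <- with_stage("detect_a_peak",
                  detect_a_peak(rate, es_time, e$time_ms,
                                refine = config$refine_peaks,
                                dense = dense_refine, min_peak = min_peak))
  fused <- nrow(a) == 0

  if (!is.null(dense_refine)) {
    dense_vol <- trig_dense_eval(curve$time_ms, curve$volume_ml, rr,
                                 length(dense$time_ms))
    dense_vol <- tibble::tibble(time_ms = dense_vol$t, volume_ml = dense_vol$y)
    dt_rate <- dense
    dt_frame <- which.min(abs(dense$time_ms - e$time_ms))
  } else {
    dense_vol <- NULL
    dt_rate <- rate
    dt_frame <- e$frame
  }
  dt <- with_stage("deceleration_time",
                   deceleration_time(dt_rate, e$time_ms, e_frame = dt_frame,
                                     method = config$dt_method))
  dvr <- with_stage("diastolic_volume_recovery",
                    diastolic_volume_recovery(curve, es_time, dense = dense_vol))

  window_end <- es_time + config$eprime_window_frac * (rr - es_time)
  if (!fused) window_end <- min(window_end, a$trough_time_ms)

  ep <- function(track) {
    if (is.null(track)) return(NA_real_)
    with_stage("early_relaxation_rate",
               early_relaxation_rate(track, es_time, window_end,
                                     refine = config$refine_peaks))
  }
  ep_sep <- ep(septal)
  ep_lat <- ep(lateral)
  ep_mean <- mean(c(ep_sep, ep_lat))
  ee_sep <- if (is.na(ep_sep)) NA_real_ else e_over_eprime(e$e_ml_s, ep_sep)
  ee_lat <- if (is.na(ep_lat)) NA_real_ else e_over_eprime(e$e_ml_s, ep_lat)
  ee_mean <- if (is.na(ep_mean)) NA_real_ else if (config$ee_mean_mode == "mean_of_ratios") {
    mean(c(ee_sep, ee_lat))
  } else {
    e_over_eprime(e$e_ml_s, ep_mean)
  }

  indices <- tibble::tibble(
    e_ml_s = e$e_ml_s,
    a_ml_s = if (fused) NA_real_ else a$a_ml_s,
    ne_per_s = normalize_peak(e$e_ml_s, edv),
    na_per_s = if (fused) NA_real_ else normalize_peak(a$a_ml_s, edv),
    ea = ea_ratio(e$e_ml_s, if (fused) NA_real_ else a$a_ml_s),
    dt_ms = dt,
    rtpe_ms = e$rtpe_ms,
    rtpa_ms = if (fused) NA_real_ else a$rtpa_ms,
    dvr_ms = dvr,
    eprime_septal_mm_s = ep_sep,
    eprime_lateral_mm_s = ep_lat,
    eprime_mean_mm_s = ep_mean,
    ee_septal_ml_mm = ee_sep,
    ee_lateral_ml_mm = ee_lat,
    ee_mean_ml_mm = ee_mean,
    edv_ml = edv,
    esv_ml = esv,
    sv_ml = sv,
    es_time_ms = es_time,
    rr_interval_ms = rr,
    fused_ea = fused
  )

  markers <- tibble::tibble(
    event = c("ES", "E peak", if (!fused) "A peak", "DVR"),
    time_ms = c(es_time, e$time_ms, if (!fused) a$time_ms, es_time + dvr)
  )

  structure(
    list(indices = indices, curve = curve, rate = rate, markers = markers,
         es_time = es_time, config = config),
    class = "diastolic_fit"
  )
}

#' @exportS3Method generics::glance
glance.diastolic_fit <- function(x, ...) x$indices

#' @exportS3Method generics::tidy
tidy.diastolic_fit <- function(x, ...) {
  tidyr::pivot_longer(x$indices, dplyr::everything(),
                      names_to = "index", values_to = "value",
                      values_transform = as.numeric)
}

#' @export
print.diastolic_fit <- function(x, ...) {
  ind <- x$indices
  cat("Diastolic analysis of one LV cycle\n")
  cat(sprintf("  RR %.0f ms, %d frames; EDV %.1f mL, ESV %.1f mL, SV %.1f mL\n",
              ind$rr_interval_ms, nrow(x$curve), ind$edv_ml, ind$esv_ml, ind$sv_ml))
  cat(sprintf("  E %.1f mL/s (NE %.2f 1/s) at ES+%.0f ms; ", ind$e_ml_s,
              ind$ne_per_s, ind$rtpe_ms))
  if (isTRUE(ind$fused_ea)) cat("A absent (fused filling)\n")
  else cat(sprintf("A %.1f mL/s at ES+%.0f ms; E/A %.2f\n", ind$a_ml_s,
                   ind$rtpa_ms, ind$ea))
  cat(sprintf("  DT %.0f ms, DVR %.0f ms\n", ind$dt_ms, ind$dvr_ms))
  if (!is.na(ind$eprime_mean_mm_s)) {
    cat(sprintf("  E' septal %.1f, lateral %.1f mm/s; mean E/E' %.2f mL/mm\n",
                ind$eprime_septal_mm_s, ind$eprime_lateral_mm_s, ind$ee_mean_ml_mm))
  }
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.diastolic_fit <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(time_ms = object$curve$time_ms,
                   value = object$curve$volume_ml, panel = "LV volume (mL)"),
    tibble::tibble(time_ms = object$rate$time_ms,
                   value = object$rate$rate_ml_s, panel = "Filling rate (mL/s)")
  )
  df$panel <- factor(df$panel, levels = c("LV volume (mL)", "Filling rate (mL/s)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c3e50") +
    ggplot2::geom_vline(data = object$markers,
                        ggplot2::aes(xintercept = .data$time_ms,
                                     colour = .data$event),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time from R wave (ms)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
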