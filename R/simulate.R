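# Synthetic physiology with closed-form ground truth: raised-cosine lobe
# filling-rate model for volume curves, matching annulus tracks, and a
# grade-conditional cohort generator.

#' Parameters for a simulated LV volume curve
#'
#' The continuous model is a filling-rate curve built from compact-support
#' raised-cosine lobes -- one negative ejection lobe during systole and one
#' (fused) or two (E + A) positive filling lobes in diastole -- integrated
#' from EDV. Compact support keeps every derived index (peak values and
#' times, deceleration time, diastolic volume recovery) analytically
#' tractable, and the lobe areas balance exactly, so the cycle closes by
#' construction.
#'
#' Amplitudes may be given directly (mL/s); when omitted they are derived
#' from the stroke volume and the early filling fraction
#' (`e_amp = e_frac * sv / e_width`, `a_amp = (1 - e_frac) * sv / a_width`).
#' When both amplitudes are given, the realised stroke volume is their total
#' lobe area and the `sv` argument is ignored. `a_amp = 0` produces a fused
#' single-lobe filling pattern.
#'
#' @param rr R-R interval, ms.
#' @param n_frames Number of reconstructed frames per cycle.
#' @param edv End-diastolic volume, mL.
#' @param sv Stroke volume, mL (target lobe area; see above).
#' @param es_time End-systolic time, ms after the R wave.
#' @param e_center,a_center Lobe peak times, ms after end-systole.
#' @param e_width,a_width Lobe half-widths, ms (support is center +/- width).
#' @param e_amp,a_amp Peak filling rates, mL/s, or `NULL` to derive.
#' @param e_frac Fraction of the stroke volume refilled by the E lobe when
#'   amplitudes are derived.
#' @param iso_delay Isovolumic delay before ejection begins, ms.
#' @param noise_sd Gaussian volume noise SD, mL (0 = noiseless).
#' @return A list of class `curve_params`.
#' @export
curve_params <- function(rr = 940, n_frames = 30, edv = 106.8, sv = 73,
                         es_time = 330, e_center = 195, e_width = 180,
                         a_center = 490, a_width = 105,
                         e_amp = NULL, a_amp = NULL, e_frac = 0.65,
                         iso_delay = 40, noise_sd = 0) {
  if (e_width <= 0 || a_width <= 0) {
    abort("Lobe widths must be positive.", class = "lvd_error_parameter")
  }
  if (es_time <= iso_delay || es_time >= rr) {
    abort("`es_time` must lie inside (iso_delay, rr).", class = "lvd_error_parameter")
  }
  if (is.null(e_amp)) e_amp <- 1000 * e_frac * sv / e_width
  if (is.null(a_amp)) a_amp <- 1000 * (1 - e_frac) * sv / a_width
  if (e_amp <= 0 || a_amp < 0) {
    abort("`e_amp` must be positive and `a_amp` non-negative.",
          class = "lvd_error_parameter")
  }
  sv <- (e_amp * e_width + a_amp * a_width) / 1000 # realised lobe area
  if (sv >= edv) {
    abort("Stroke volume must be smaller than EDV.", class = "lvd_error_parameter")
  }
  if (e_center < e_width) {
    abort("The E lobe overlaps ejection (need e_center >= e_width).",
          class = "lvd_error_parameter")
  }
  fused <- a_amp == 0
  if (!fused) {
    if (a_center - a_width < e_center + e_width) {
      abort("The A lobe overlaps the E lobe.", class = "lvd_error_parameter")
    }
    if (es_time + a_center + a_width > rr) {
      abort("The A lobe extends past the R-R interval.", class = "lvd_error_parameter")
    }
  } else if (es_time + e_center + e_width > rr) {
    abort("The E lobe extends past the R-R interval.", class = "lvd_error_parameter")
  }
  structure(
    list(rr = rr, n_frames = n_frames, edv = edv, sv = sv, es_time = es_time,
         e_center = e_center, e_width = e_width, a_center = a_center,
         a_width = a_width, e_amp = e_amp, a_amp = a_amp,
         iso_delay = iso_delay, noise_sd = noise_sd),
    class = "curve_params"
  )
}

# Continuous model pieces (times absolute, ms; rates mL/ms).
curve_model <- function(p) {
  ej_width <- (p$es_time - p$iso_delay) / 2
  ej_center <- (p$es_time + p$iso_delay) / 2
  ej_amp <- p$sv / ej_width
  e_c <- p$es_time + p$e_center
  a_c <- p$es_time + p$a_center
  list(
    volume = function(t) {
      p$edv - raised_cosine_cum(t, ej_amp, ej_center, ej_width) +
        raised_cosine_cum(t, p$e_amp / 1000, e_c, p$e_width) +
        (if (p$a_amp > 0) raised_cosine_cum(t, p$a_amp / 1000, a_c, p$a_width) else 0)
    },
    rate = function(t) {
      -raised_cosine(t, ej_amp, ej_center, ej_width) +
        raised_cosine(t, p$e_amp / 1000, e_c, p$e_width) +
        (if (p$a_amp > 0) raised_cosine(t, p$a_amp / 1000, a_c, p$a_width) else 0)
    },
    filled = function(t) { # volume recovered since end-systole
      raised_cosine_cum(t, p$e_amp / 1000, e_c, p$e_width) +
        (if (p$a_amp > 0) raised_cosine_cum(t, p$a_amp / 1000, a_c, p$a_width) else 0)
    }
  )
}

# Least-squares deceleration time of a raised-cosine downslope, in closed
# form: the continuous fit over [peak, peak + width] crosses zero at
# width * (pi^2 + 12) / 24 after the peak.
raised_cosine_dt <- function(width) width * (pi^2 + 12) / 24

#' Simulate a volume curve with analytic ground truth
#'
#' Samples the continuous raised-cosine model of [curve_params()] on the
#' frame grid, optionally adding Gaussian volume noise, and returns the
#' index values implied by the continuous model (not by the samples):
#' peak rates and times, NE/NA, E/A, the closed-form least-squares
#' deceleration time of the cosine downslope, and the exact 80%%
#' stroke-volume recovery time.
#'
#' @param params A [curve_params()].
#' @param seed Optional seed for the noise draws.
#' @return List with elements `curve` (a [volume_curve()]), `truth` (one-row
#'   tibble of ground-truth indices) and `params`.
#' @examples
#' sim <- simulate_volume_curve(curve_params(noise_sd = 0), seed = 1)
#' sim$truth
#' @export
simulate_volume_curve <- function(params, seed = NULL) {
  stopifnot(inherits(params, "curve_params"))
  if (!is.null(seed)) set.seed(seed)
  p <- params
  mdl <- curve_model(p)
  times <- p$rr * (seq_len(p$n_frames) - 1) / p$n_frames
  vols <- mdl$volume(times)
  if (p$noise_sd > 0) vols <- vols + rnorm(p$n_frames, sd = p$noise_sd)
  curve <- volume_curve(tibble::tibble(time_ms = times, volume_ml = vols),
                        rr_interval = p$rr)

  fused <- p$a_amp == 0
  dvr_target <- 0.8 * p$sv
  dvr <- uniroot(function(t) mdl$filled(t) - dvr_target,
                 lower = p$es_time, upper = p$rr, tol = 1e-9)$root - p$es_time
  truth <- tibble::tibble(
    e_ml_s = p$e_amp,
    a_ml_s = if (fused) NA_real_ else p$a_amp,
    ne_per_s = p$e_amp / p$edv,
    na_per_s = if (fused) NA_real_ else p$a_amp / p$edv,
    ea = if (fused) NA_real_ else p$e_amp / p$a_amp,
    dt_ms = raised_cosine_dt(p$e_width),
    rtpe_ms = p$e_center,
    rtpa_ms = if (fused) NA_real_ else p$a_center,
    dvr_ms = dvr,
    edv_ml = p$edv,
    esv_ml = p$edv - p$sv,
    sv_ml = p$sv,
    es_time_ms = p$es_time
  )
  list(curve = curve, truth = truth, params = p)
}

#' Simulate an apex-annulus distance track with known E'
#'
#' The annular velocity is modelled with the same raised-cosine machinery:
#' a systolic shortening lobe, an early lengthening lobe whose peak is
#' exactly `eprime_true`, and a small atrial lengthening lobe; the areas
#' balance so the track closes over the cycle. The continuous maximum
#' early-diastolic lengthening rate equals `eprime_true` by construction.
#'
#' @param eprime_true Ground-truth early relaxation rate, mm/s.
#' @param es_time End-systolic time, ms.
#' @param rr R-R interval, ms.
#' @param n_frames Frames per cycle.
#' @param site `"septal"` or `"lateral"`.
#' @param base_mm Apex-annulus distance at end-diastole, mm.
#' @param e_center,e_width Early lobe peak time (ms after ES) and half-width.
#' @param a_frac Atrial lobe amplitude as a fraction of `eprime_true`
#'   (0 = no atrial lengthening).
#' @param jitter_sd Gaussian distance jitter SD, mm.
#' @param seed Optional seed for the jitter.
#' @return An [annulus_track()] with attribute `eprime_true`.
#' @export
simulate_annulus_track <- function(eprime_true, es_time, rr, n_frames = 30,
                                   site = c("septal", "lateral"),
                                   base_mm = 95, e_center = 150, e_width = 140,
                                   a_frac = 0.3, jitter_sd = 0, seed = NULL) {
  site <- match.arg(site)
  if (eprime_true <= 0) {
    abort("`eprime_true` must be positive.", class = "lvd_error_parameter")
  }
  if (!is.null(seed)) set.seed(seed)
  ep <- eprime_true / 1000 # mm/ms
  e_c <- es_time + e_center
  if (e_c - e_width < es_time) {
    abort("The early lobe overlaps systole (need e_center >= e_width).",
          class = "lvd_error_parameter")
  }
  a_width <- 70
  a_c <- rr - a_width - 10
  a_amp <- a_frac * ep
  if (a_amp > 0 && a_c - a_width < e_c + e_width) {
    abort("The atrial lobe overlaps the early lobe; shorten `e_width` or `e_center`.",
          class = "lvd_error_parameter")
  }
  length_area <- ep * e_width + a_amp * a_width
  sh_width <- (es_time - 20) / 2
  sh_center <- (es_time + 20) / 2
  sh_amp <- length_area / sh_width

  times <- rr * (seq_len(n_frames) - 1) / n_frames
  d <- base_mm - raised_cosine_cum(times, sh_amp, sh_center, sh_width) +
    raised_cosine_cum(times, ep, e_c, e_width) +
    (if (a_amp > 0) raised_cosine_cum(times, a_amp, a_c, a_width) else 0)
  if (jitter_sd > 0) d <- d + rnorm(n_frames, sd = jitter_sd)
  out <- annulus_track(tibble::tibble(time_ms = times, distance_mm = d),
                       site = site, rr_interval = rr)
  attr(out, "eprime_true") <- eprime_true
  out
}

# Grade-conditional target moments for the cohort generator. Units follow
# the column names; props are per-grade prevalences.
cohort_targets <- function() {
  g <- c("normal", "type I", "type II")
  long <- function(variable, means, sds) {
    tibble::tibble(variable = variable, grade = g, mean = means, sd = sds)
  }
  dplyr::bind_rows(
    long("age", c(66.8, 65.5, 64.4), c(8.9, 7.5, 9.7)),
    long("lv_mass_g", c(124.8, 132.5, 121.8), c(34.4, 38.2, 26.2)),
    long("bsa_m2", c(1.8, 1.8, 1.8), c(0.2, 0.2, 0.2)),
    long("hr_cmr", c(65.2, 66.4, 61.6), c(10.4, 9.7, 5.5)),
    long("echo_e_cm_s", c(74.53, 74.89, 87.68), c(16.43, 20.76, 20.94)),
    long("echo_dt_ms", c(220.14, 247.95, 258.4), c(45.19, 76.70, 77.69)),
    long("echo_ea", c(0.99, 1.02, 1.23), c(0.24, 0.22, 0.47)),
    long("echo_eprime_septal", c(9.38, 8.33, 6.00), c(1.69, 2.12, 1.26)),
    long("echo_eprime_lateral", c(11.61, 8.23, 6.97), c(2.45, 1.68, 1.80)),
    long("echo_tpe_ms", rep(550.77, 3), rep(196.19, 3)),
    long("echo_tpa_ms", rep(181.5, 3), rep(27.45, 3)),
    long("cmr_e_ml_s", c(189.30, 206.30, 213.60), c(66.39, 62.58, 71.67)),
    long("cmr_dt_ms", c(186.61, 211.08, 218.37), c(43.94, 43.75, 42.59)),
    long("cmr_tpe_ms", c(504.86, 493.46, 517.54), c(82.41, 68.75, 37.80)),
    long("cmr_tpa_ms", c(837.27, 861.57, 866.00), c(193.40, 155.17, 115.64)),
    long("cmr_ea", c(1.10, 1.01, 1.33), c(0.38, 0.26, 0.45)),
    long("cmr_dvr_ms", c(535.32, 542.44, 516.08), c(117.96, 122.45, 78.16)),
    long("cmr_edv_ml", c(106.8, 110.6, 99.6), c(24.4, 28.7, 22.1)),
    long("cmr_eprime_septal", c(75.35, 66.49, 58.22), c(24.49, 25.31, 24.11)),
    long("cmr_eprime_lateral", c(82.36, 70.88, 61.06), c(26.14, 28.45, 27.73))
  )
}

cohort_props <- function() {
  tibble::tibble(
    variable = rep(c("male", "hypertension", "diabetes"), each = 3),
    grade = rep(c("normal", "type I", "type II"), 3),
    prob = c(0.393, 0.333, 0.400,
             0.500, 0.333, 0.600,
             0.045, 0.095, 0.200)
  )
}

#' Parameters for a simulated validation cohort
#'
#' Defaults emulate the grade mix (64.7%% normal, 20.6%% impaired, 14.7%%
#' reduced) and the grade-conditional means and SDs of the observed echo and
#' CMR variables, with the configured echo-vs-CMR E/A cross-modality
#' correlation. Cross-variable correlations other than E/A default to zero:
#' the published summaries fix the marginals, not the joint distribution.
#'
#' @param n Cohort size.
#' @param grade_probs Probabilities of normal / type I / type II.
#' @param targets Long tibble `variable, grade, mean, sd` of grade-
#'   conditional moments (default: the built-in anchors).
#' @param props Long tibble `variable, grade, prob` of binary prevalences.
#' @param ea_cross_corr Correlation between echo and CMR E/A within grade.
#' @param hr_diff_sd SD of the same-day echo-minus-CMR heart-rate
#'   difference, beats/min (same-day studies differ by a few beats only).
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n = 102,
                          grade_probs = c(0.647, 0.206, 0.147),
                          targets = cohort_targets(),
                          props = cohort_props(),
                          ea_cross_corr = 0.71,
                          hr_diff_sd = 4) {
  if (abs(sum(grade_probs) - 1) > 1e-8 || any(grade_probs < 0)) {
    abort("`grade_probs` must be non-negative and sum to 1.",
          class = "lvd_error_parameter")
  }
  if (abs(ea_cross_corr) > 1) {
    abort("`ea_cross_corr` must lie in [-1, 1].", class = "lvd_error_parameter")
  }
  if (any(targets$sd < 0)) {
    abort("Target SDs must be non-negative.", class = "lvd_error_parameter")
  }
  structure(
    list(n = n, grade_probs = grade_probs, targets = targets, props = props,
         ea_cross_corr = ea_cross_corr, hr_diff_sd = hr_diff_sd),
    class = "cohort_params"
  )
}

# Truncated-normal draw: +/- 3 SD and strictly positive (all simulated
# physiological variables are positive quantities).
rtruncnorm1 <- function(n, mean, sd, lower = pmax(mean - 3 * sd, .Machine$double.eps),
                        upper = mean + 3 * sd) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

# Deterministic per-subject substream: subjects can be regenerated
# individually without replaying the whole cohort stream.
subject_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(i)) %% 2147483647)
}

#' Simulate a paired echo/CMR validation cohort
#'
#' Per subject: a true grade is drawn from the grade mix; every echo and CMR
#' variable is drawn from its grade-conditional truncated normal; the echo
#' and CMR E/A ratios are drawn jointly with the configured cross-modality
#' correlation; A velocities/rates are derived from E and E/A, and NE/NA
#' from E, A and EDV (so the normalisation identity holds exactly); heart
#' rates of the two same-day studies differ by a small Gaussian amount.
#' Identical `seed` gives a byte-identical cohort, and each subject has its
#' own deterministic substream.
#'
#' @param params A [cohort_params()].
#' @param seed Integer seed.
#' @return A tibble with one row per subject: `id`, `grade_true`,
#'   covariates, echo and CMR measures (including derived ratios).
#' @examples
#' sc <- simulate_cohort(cohort_params(n = 50), seed = 7)
#' dplyr::count(sc, grade_true)
#' @export
simulate_cohort <- function(params = cohort_params(), seed = 1) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n
  grades <- grade_levels()
  empty <- n == 0
  set.seed(seed)
  grade_true <- if (empty) factor(character(0), levels = grades) else
    factor(sample(grades, n, replace = TRUE, prob = params$grade_probs),
           levels = grades)

  tg <- params$targets
  moment <- function(variable, grade) {
    row <- tg[tg$variable == variable & tg$grade == grade, ]
    c(mean = row$mean, sd = row$sd)
  }
  prop <- function(variable, grade) {
    params$props$prob[params$props$variable == variable &
                        params$props$grade == grade]
  }

  rows <- purrr::map(seq_len(n), function(i) {
    g <- as.character(grade_true[i])
    set.seed(subject_seed(seed, i))
    draw <- function(variable) {
      m <- moment(variable, g)
      rtruncnorm1(1, m["mean"], m["sd"])
    }
    # jointly-drawn E/A pair (echo predicts CMR with correlation r)
    r <- params$ea_cross_corr
    z1 <- rnorm(1); z2 <- rnorm(1)
    me <- moment("echo_ea", g); mc <- moment("cmr_ea", g)
    echo_ea <- max(me["mean"] + me["sd"] * pmax(pmin(z1, 3), -3), 0.2)
    cmr_ea <- max(mc["mean"] + mc["sd"] *
                    pmax(pmin(r * z1 + sqrt(1 - r^2) * z2, 3), -3), 0.2)
    hr_cmr <- draw("hr_cmr")
    hr_echo <- hr_cmr + rnorm(1, 0, params$hr_diff_sd)
    vals <- tibble::tibble(
      id = sprintf("S%04d", i),
      grade_true = g,
      age = draw("age"),
      sex = if (runif(1) < prop("male", g)) "male" else "female",
      hypertension = runif(1) < prop("hypertension", g),
      diabetes = runif(1) < prop("diabetes", g),
      lv_mass_g = draw("lv_mass_g"),
      bsa_m2 = draw("bsa_m2"),
      hr_cmr = hr_cmr,
      hr_echo = hr_echo,
      echo_e_cm_s = draw("echo_e_cm_s"),
      echo_dt_ms = draw("echo_dt_ms"),
      echo_ea = echo_ea,
      echo_eprime_septal = draw("echo_eprime_septal"),
      echo_eprime_lateral = draw("echo_eprime_lateral"),
      echo_tpe_ms = draw("echo_tpe_ms"),
      echo_tpa_ms = draw("echo_tpa_ms"),
      cmr_e_ml_s = draw("cmr_e_ml_s"),
      cmr_dt_ms = draw("cmr_dt_ms"),
      cmr_tpe_ms = draw("cmr_tpe_ms"),
      cmr_tpa_ms = draw("cmr_tpa_ms"),
      cmr_ea = cmr_ea,
      cmr_dvr_ms = draw("cmr_dvr_ms"),
      cmr_edv_ml = draw("cmr_edv_ml"),
      cmr_eprime_septal = draw("cmr_eprime_septal"),
      cmr_eprime_lateral = draw("cmr_eprime_lateral")
    )
    vals
  })
  out <- if (empty) cohort_prototype() else dplyr::bind_rows(rows)
  out$grade_true <- factor(out$grade_true, levels = grades)
  dplyr::mutate(
    out,
    lvmi = .data$lv_mass_g / .data$bsa_m2,
    rr_echo_ms = 60000 / .data$hr_echo,
    rr_cmr_ms = 60000 / .data$hr_cmr,
    echo_a_cm_s = .data$echo_e_cm_s / .data$echo_ea,
    echo_eprime_mean = (.data$echo_eprime_septal + .data$echo_eprime_lateral) / 2,
    echo_ee_septal = .data$echo_e_cm_s / .data$echo_eprime_septal,
    echo_ee_lateral = .data$echo_e_cm_s / .data$echo_eprime_lateral,
    echo_ee_mean = .data$echo_e_cm_s / .data$echo_eprime_mean,
    cmr_a_ml_s = .data$cmr_e_ml_s / .data$cmr_ea,
    cmr_ne = .data$cmr_e_ml_s / .data$cmr_edv_ml,
    cmr_na = .data$cmr_a_ml_s / .data$cmr_edv_ml,
    cmr_eprime_mean = (.data$cmr_eprime_septal + .data$cmr_eprime_lateral) / 2,
    cmr_ee_septal = .data$cmr_e_ml_s / .data$cmr_eprime_septal,
    cmr_ee_lateral = .data$cmr_e_ml_s / .data$cmr_eprime_lateral,
    cmr_ee_mean = (.data$cmr_ee_septal + .data$cmr_ee_lateral) / 2
  )
}

# Zero-row cohort with the full column set (n = 0 draws nothing).
cohort_prototype <- function() {
  tibble::tibble(
    id = character(0), grade_true = character(0), age = numeric(0),
    sex = character(0), hypertension = logical(0), diabetes = logical(0),
    lv_mass_g = numeric(0), bsa_m2 = numeric(0), hr_cmr = numeric(0),
    hr_echo = numeric(0), echo_e_cm_s = numeric(0), echo_dt_ms = numeric(0),
    echo_ea = numeric(0), echo_eprime_septal = numeric(0),
    echo_eprime_lateral = numeric(0), echo_tpe_ms = numeric(0),
    echo_tpa_ms = numeric(0), cmr_e_ml_s = numeric(0), cmr_dt_ms = numeric(0),
    cmr_tpe_ms = numeric(0), cmr_tpa_ms = numeric(0), cmr_ea = numeric(0),
    cmr_dvr_ms = numeric(0), cmr_edv_ml = numeric(0),
    cmr_eprime_septal = numeric(0), cmr_eprime_lateral = numeric(0)
  )
}

#' Curve parameters implied by one simulated subject
#'
#' Maps a cohort row (drawn CMR measures) onto [curve_params()] so that a
#' per-subject volume curve can be generated whose ground-truth E, A and EDV
#' equal the drawn values. Lobe widths and timings scale with the subject's
#' diastolic interval; amplitudes are capped so the implied stroke volume
#' stays below 85% of EDV.
#'
#' @param subject One cohort row (tibble or list) with `rr_cmr_ms`,
#'   `cmr_edv_ml`, `cmr_e_ml_s`, `cmr_a_ml_s`.
#' @param n_frames Frames per cycle.
#' @param noise_sd Volume noise SD, mL.
#' @return A [curve_params()].
#' @export
subject_curve_params <- function(subject, n_frames = 30, noise_sd = 0) {
  rr <- subject$rr_cmr_ms
  es <- 0.35 * rr
  avail <- rr - es
  e_w <- 0.30 * avail
  a_w <- 0.16 * avail
  e_amp <- subject$cmr_e_ml_s
  a_amp <- subject$cmr_a_ml_s
  sv <- (e_amp * e_w + a_amp * a_w) / 1000
  cap <- 0.85 * subject$cmr_edv_ml
  if (sv > cap) {
    scale <- cap / sv
    e_amp <- e_amp * scale
    a_amp <- a_amp * scale
  }
  curve_params(
    rr = rr, n_frames = n_frames, edv = subject$cmr_edv_ml,
    es_time = es,
    e_center = e_w + 0.02 * avail, e_width = e_w,
    a_center = avail - a_w - 0.02 * avail, a_width = a_w,
    e_amp = e_amp, a_amp = a_amp, noise_sd = noise_sd
  )
}
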