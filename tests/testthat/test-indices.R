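# Diastolic filling indices: peak detection, deceleration time, diastolic
# volume recovery, normalisation, and the analyze_curve orchestrator.

# Bare filling-rate curve for component tests that bypass differentiation.
make_rate <- function(times, rates, rr, sv = 50) {
  out <- tibble::tibble(time_ms = times, rate_ml_s = rates)
  attr(out, "rr_interval") <- rr
  attr(out, "sv_ml") <- sv
  class(out) <- c("filling_rate_curve", class(out))
  out
}

test_that("E is the first post-ES filling-rate maximum", {
  # two-lobe cycle with amplitudes near observed normal means: first lobe
  # 189 mL/s at ES+150 ms, second 181 mL/s -- E must be the first, not the max
  p <- curve_params(rr = 940, es_time = 330, e_amp = 189, e_center = 150,
                    e_width = 130, a_amp = 181, a_center = 470, a_width = 100,
                    edv = 110)
  sim <- simulate_volume_curve(p)
  rate <- derive_filling_rate(sim$curve)
  dense <- dense_filling_rate(sim$curve)
  e <- detect_e_peak(rate, 330, dense = dense)
  expect_equal(e$e_ml_s, 189, tolerance = 0.01)
  expect_equal(e$rtpe_ms, 150, tolerance = 940 / 30 / 2)

  # dense-grid peak oracle: on a 1 ms grid the sampled max is the lobe peak
  t1 <- seq(0, 939, by = 1)
  r1 <- 1000 * (oracle_lobe(t1, 0.189, 480, 130) + oracle_lobe(t1, 0.181, 800, 100))
  dense_rate <- make_rate(t1, r1, 940)
  e1 <- detect_e_peak(dense_rate, 330, refine = FALSE)
  expect_equal(e1$e_ml_s, 189)
  expect_equal(e1$time_ms, 480)
})

test_that("E detection warns and uses the boundary sample on monotone rates", {
  t <- seq(0, 580, by = 20)
  r <- ifelse(t < 300, -50, 200 * exp(-(t - 300) / 150)) # peak sits on ES itself
  rate <- make_rate(t, r, 600)
  expect_warning(e <- detect_e_peak(rate, 300, refine = FALSE),
                 class = "lvd_warning_boundary_peak")
  expect_equal(e$time_ms, 320) # first sample after ES

  flat <- make_rate(t, ifelse(t <= 300, -50, 0), 600)
  expect_error(detect_e_peak(flat, 300), class = "lvd_error_no_filling")
})

test_that("A is the first maximum after the post-E trough, or absent", {
  p <- curve_params(rr = 940, es_time = 330, e_amp = 189, e_center = 150,
                    e_width = 130, a_amp = 181, a_center = 470, a_width = 100,
                    edv = 110)
  sim <- simulate_volume_curve(p)
  rate <- derive_filling_rate(sim$curve)
  dense <- dense_filling_rate(sim$curve)
  e <- detect_e_peak(rate, 330, dense = dense)
  a <- detect_a_peak(rate, 330, e$time_ms, dense = dense)
  expect_equal(a$a_ml_s, 181, tolerance = 0.015)
  expect_equal(a$rtpa_ms, 470, tolerance = 940 / 30)

  # fused single lobe: absent A
  pf <- curve_params(rr = 940, es_time = 330, e_amp = 250, e_center = 250,
                     e_width = 240, a_amp = 0, edv = 110)
  simf <- simulate_volume_curve(pf)
  ratef <- derive_filling_rate(simf$curve)
  ef <- detect_e_peak(ratef, 330)
  expect_equal(nrow(detect_a_peak(ratef, 330, ef$time_ms)), 0)

  # three maxima after ES: A is the first after the E-lobe trough, not the max
  t1 <- seq(0, 1199, by = 10)
  r3 <- 1000 * (oracle_lobe(t1, 0.2, 450, 80) + oracle_lobe(t1, 0.15, 700, 80) +
                  oracle_lobe(t1, 0.18, 1000, 80))
  rate3 <- make_rate(t1, r3, 1200)
  e3 <- detect_e_peak(rate3, 330, refine = FALSE)
  a3 <- detect_a_peak(rate3, 330, e3$time_ms, refine = FALSE)
  maxima_oracle <- t1[which(diff(sign(diff(r3))) == -2)] + 10
  expect_equal(e3$time_ms, 450)
  expect_equal(a3$time_ms, 700)
  expect_equal(a3$a_ml_s, 150)
  expect_gt(length(maxima_oracle), 2)
})

test_that("peak normalisation and E/A behave like plain ratios", {
  expect_equal(normalize_peak(200, 100), 2)
  expect_equal(round(normalize_peak(189.30, 106.8), 2), 1.77)
  expect_equal(normalize_peak(0, 50), 0)
  expect_error(normalize_peak(100, 0), class = "lvd_error_argument")

  expect_equal(ea_ratio(150, 150), 1)
  expect_equal(ea_ratio(150, 100), 1.5)
  expect_true(is.na(ea_ratio(150, NA)))
  expect_error(ea_ratio(150, -1), class = "lvd_error_argument")
  set.seed(1)
  e <- runif(20, 50, 300); a <- runif(20, 50, 300)
  expect_equal(ea_ratio(e, a), e / a)
})

test_that("deceleration time extrapolates the downslope to baseline", {
  # linear fall 200 mL/s at 400 ms to 0 at 600 ms: DT = 200 exactly
  t <- seq(0, 760, by = 20)
  r <- ifelse(t < 300, -100,
              ifelse(t < 400, (t - 300) * 2, pmax(200 - (t - 400), 0)))
  rate <- make_rate(t, r, 800)
  expect_equal(deceleration_time(rate, 400), 200)
  # chord through first/last downslope sample agrees on a straight limb
  expect_equal(deceleration_time(rate, 400, method = "chord"), 200)
  # scaling all rates leaves DT unchanged
  expect_equal(deceleration_time(make_rate(t, 3.7 * r, 800), 400), 200)
  # time translation invariance
  rate_shift <- make_rate(t + 500, r, 800)
  expect_equal(deceleration_time(rate_shift, 900), 200)

  # raised-cosine lobe, 30 ms sampling vs the identical 1 ms procedure
  lobe <- function(t) 1000 * oracle_lobe(t, 0.2, 450, 120)
  t30 <- seq(0, 870, by = 30)
  dt30 <- deceleration_time(make_rate(t30, lobe(t30), 900), 450,
                            e_frame = which.min(abs(t30 - 450)))
  dt1 <- oracle_dense_dt(lobe, 450, 700)
  expect_lt(abs(dt30 - dt1), 30)

  short <- make_rate(c(0, 30, 60, 90, 120, 150, 180, 210),
                     c(5, 4, 200, 210, 220, 230, 240, 250), 240)
  expect_error(deceleration_time(short, 0, e_frame = 3),
               class = "lvd_error_insufficient_samples")
})

test_that("diastolic volume recovery interpolates the 80% crossing", {
  # linear refill ESV -> EDV over 400 ms after ES: DVR = 0.8 * 400 = 320
  rr <- 1000
  t <- seq(0, 975, by = 25)
  v <- ifelse(t < 300, 100 - 0.15 * t,
              ifelse(t <= 700, 55 + 45 * (t - 300) / 400, 100))
  vc <- volume_curve(tibble::tibble(time_ms = t, volume_ml = v), rr)
  expect_equal(diastolic_volume_recovery(vc, 300), 320)

  # cosine refill: closed-form crossing at (T/pi) * acos(-0.6)
  Tr <- 400
  vcos <- ifelse(t < 300, 100 - 0.15 * t,
                 ifelse(t <= 700, 55 + 45 * (1 - cos(pi * (t - 300) / Tr)) / 2, 100))
  vc2 <- volume_curve(tibble::tibble(time_ms = t, volume_ml = vcos), rr)
  dvr_true <- (Tr / pi) * acos(-0.6)
  expect_equal(diastolic_volume_recovery(vc2, 300), dvr_true, tolerance = 0.02)

  # never recovering to the threshold is an explicit error
  vlow <- ifelse(t < 300, 100 - 0.15 * t, 55 + pmin(45 * 0.5, 45 * 0.5 * (t - 300) / 100))
  vc3 <- volume_curve(tibble::tibble(time_ms = t, volume_ml = vlow), rr)
  expect_error(diastolic_volume_recovery(vc3, 300), class = "lvd_error_no_recovery")
})

test_that("analyze_curve assembles consistent indices", {
  p <- curve_params()
  sim <- simulate_volume_curve(p)
  septal <- simulate_annulus_track(70, es_time = p$es_time, rr = p$rr,
                                   site = "septal")
  lateral <- simulate_annulus_track(82, es_time = p$es_time, rr = p$rr,
                                    site = "lateral")
  fit <- analyze_curve(sim$curve, septal = septal, lateral = lateral)
  ind <- glance(fit)

  expect_equal(ind$e_ml_s, sim$truth$e_ml_s, tolerance = 0.02)
  expect_equal(ind$a_ml_s, sim$truth$a_ml_s, tolerance = 0.02)
  expect_equal(ind$dvr_ms, sim$truth$dvr_ms, tolerance = 0.05)
  # the normalisation identity holds on the stored values
  expect_equal(ind$ne_per_s * ind$edv_ml, ind$e_ml_s, tolerance = 1e-12)
  expect_equal(ind$na_per_s * ind$edv_ml, ind$a_ml_s, tolerance = 1e-12)
  expect_equal(ind$ea, ind$e_ml_s / ind$a_ml_s, tolerance = 1e-12)
  expect_equal(ind$eprime_septal_mm_s, 70, tolerance = 0.05)
  expect_equal(ind$eprime_lateral_mm_s, 82, tolerance = 0.05)
  expect_equal(ind$ee_septal_ml_mm, ind$e_ml_s / ind$eprime_septal_mm_s,
               tolerance = 1e-12)
  # mean E/E': mean of the site ratios by default
  expect_equal(ind$ee_mean_ml_mm,
               mean(c(ind$ee_septal_ml_mm, ind$ee_lateral_ml_mm)),
               tolerance = 1e-12)
  cfg <- analysis_config(ee_mean_mode = "ratio_of_means")
  fit2 <- analyze_curve(sim$curve, septal = septal, lateral = lateral,
                        config = cfg)
  ind2 <- glance(fit2)
  expect_equal(ind2$ee_mean_ml_mm, ind2$e_ml_s / ind2$eprime_mean_mm_s,
               tolerance = 1e-12)

  # tidy/print/autoplot surfaces
  expect_true(all(c("index", "value") %in% names(tidy(fit))))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  expect_output(print(fit), "Diastolic analysis")
})

test_that("analyze_curve flags fused filling and labels stage errors", {
  pf <- curve_params(rr = 940, es_time = 330, e_amp = 260, e_center = 280,
                     e_width = 260, a_amp = 0, edv = 110)
  simf <- simulate_volume_curve(pf)
  fitf <- analyze_curve(simf$curve)
  indf <- glance(fitf)
  expect_true(indf$fused_ea)
  expect_true(is.na(indf$a_ml_s) && is.na(indf$na_per_s) &&
                is.na(indf$rtpa_ms) && is.na(indf$ea))
  expect_equal(indf$e_ml_s, 260, tolerance = 0.02)

  # flat diastole: ejection then nothing. The closed-cycle wrap spreads the
  # non-physiological reset across the boundary frames, so the failure
  # surfaces downstream -- what matters is a classed error with a stage label
  t <- seq(0, 930, by = 30)
  v <- ifelse(t < 300, 100 - 0.15 * t, 55)
  vc <- volume_curve(tibble::tibble(time_ms = t, volume_ml = v), 960)
  err <- tryCatch(suppressWarnings(analyze_curve(vc)), error = function(e) e)
  expect_true(any(grepl("^lvd_error", class(err))))
  expect_match(conditionMessage(err), "^\\[")

  # a rate curve with no positive post-ES flow raises no-filling directly
  flat_rate <- make_rate(t, ifelse(t < 300, -46.5, 0), 960)
  err2 <- tryCatch(with_stage("detect_e_peak", detect_e_peak(flat_rate, 300)),
                   error = function(e) e)
  expect_s3_class(err2, "lvd_error_no_filling")
  expect_match(conditionMessage(err2), "detect_e_peak")
})

test_that("detected peak location is invariant to uniform rate scaling", {
  p <- curve_params()
  sim <- simulate_volume_curve(p)
  rate <- derive_filling_rate(sim$curve)
  e1 <- detect_e_peak(rate, p$es_time, refine = FALSE)
  scaled <- make_rate(rate$time_ms, 5 * rate$rate_ml_s, p$rr)
  e2 <- detect_e_peak(scaled, p$es_time, refine = FALSE)
  expect_equal(e2$time_ms, e1$time_ms)
  expect_equal(e2$e_ml_s, 5 * e1$e_ml_s)
})
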