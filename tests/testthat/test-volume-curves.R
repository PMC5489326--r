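# Volume-curve construction, differentiation, end-systole location, and
# mask-stack reduction.

make_curve <- function(f, rr = 900, n = 30) {
  t <- rr * (0:(n - 1)) / n
  volume_curve(tibble::tibble(time_ms = t, volume_ml = f(t)), rr_interval = rr)
}

test_that("volume_curve enforces its invariants", {
  t <- seq(0, 870, by = 30)
  v <- 70 + 30 * cos(2 * pi * t / 900)
  expect_s3_class(volume_curve(data.frame(time_ms = t, volume_ml = v), 900),
                  "volume_curve")
  expect_error(volume_curve(data.frame(t = t, v = v), 900),
               class = "lvd_error_schema")
  expect_error(volume_curve(data.frame(time_ms = t[1:5], volume_ml = v[1:5]), 900),
               class = "lvd_error_sampling")
  expect_error(volume_curve(data.frame(time_ms = rev(t), volume_ml = v), 900),
               class = "lvd_error_invariant")
  expect_error(volume_curve(data.frame(time_ms = t + 10, volume_ml = v), 900),
               class = "lvd_error_invariant")
  expect_error(volume_curve(data.frame(time_ms = t, volume_ml = v), 870),
               class = "lvd_error_invariant") # last frame not inside R-R
  expect_error(volume_curve(data.frame(time_ms = t, volume_ml = v - 100), 900),
               class = "lvd_error_invariant") # non-positive volumes
  expect_error(volume_curve(data.frame(time_ms = t, volume_ml = rep(70, 30)), 900),
               class = "lvd_error_invariant") # EDV must exceed ESV
})

test_that("temporal resolution is the R-R interval per cardiac phase", {
  expect_equal(temporal_resolution(870, 30), 29)
  expect_equal(temporal_resolution(900, 30), 30)
  expect_equal(temporal_resolution(1000, 30), 33.33, tolerance = 1e-3)
  expect_error(temporal_resolution(900, 0), class = "lvd_error_argument")
})

test_that("end-systole is the earliest minimum-volume frame", {
  v <- c(100, 90, 80, 70, 60, 50, 45, 50, 60, 70, 80, 90)
  vc <- volume_curve(tibble::tibble(time_ms = seq(0, 330, by = 30),
                                    volume_ml = v), 360)
  es <- locate_end_systole(vc)
  expect_equal(es$frame, 7)
  expect_equal(es$frame, which.min(v)) # brute-force argmin, always

  v_tie <- c(100, 80, 45, 45, 45, 60, 70, 80, 90, 95, 98, 99)
  vc_tie <- volume_curve(tibble::tibble(time_ms = seq(0, 330, by = 30),
                                        volume_ml = v_tie), 360)
  expect_equal(locate_end_systole(vc_tie)$frame, 3) # earliest of the tie

  # cosine-shaped cycle with analytic minimum at 0.4 * RR
  rr <- 900
  vc_cos <- make_curve(function(t) 100 - 20 * cos(2 * pi * (t - 0.4 * rr) / rr),
                       rr = rr, n = 32)
  es_cos <- locate_end_systole(vc_cos)
  dense_t <- seq(0, rr, by = 0.1)
  t_min <- dense_t[which.min(100 - 20 * cos(2 * pi * (dense_t - 0.4 * rr) / rr))]
  expect_equal(es_cos$frame,
               which.min(abs(vc_cos$time_ms - t_min))) # nearest sampled frame
})

test_that("central differences are cyclic, exact on lines, bounded on sines", {
  rr <- 900
  # piecewise-linear interior: slope k mL/ms appears exactly (x1000 in mL/s)
  k <- 0.12
  vc_lin <- make_curve(function(t) {
    ifelse(t < 450, 100 - k * t, 100 - k * 450 + k * (t - 450))
  }, rr = rr)
  rate <- derive_filling_rate(vc_lin)
  interior <- 3:13 # strictly inside the descending limb
  expect_equal(rate$rate_ml_s[interior], rep(-k * 1000, length(interior)))

  # sine curve: error bounded by the second-order truncation factor
  vc_sin <- make_curve(function(t) 100 + 10 * sin(2 * pi * t / rr), rr = rr)
  r_sin <- derive_filling_rate(vc_sin)
  true_rate <- 10 * (2 * pi / rr) * cos(2 * pi * vc_sin$time_ms / rr) * 1000
  x <- 2 * pi / 30
  bound <- max(abs(true_rate)) * (1 - sin(x) / x)
  expect_lt(max(abs(r_sin$rate_ml_s - true_rate)), bound * 1.01)

  # locally flat segment differentiates to zero
  vc_flat <- make_curve(function(t) ifelse(t < 300, 100 - 0.1 * t,
                                           ifelse(t < 600, 70, 70 + 0.1 * (t - 600))),
                        rr = rr)
  r_flat <- derive_filling_rate(vc_flat)
  flat_idx <- which(vc_flat$time_ms > 330 & vc_flat$time_ms < 570)
  expect_equal(r_flat$rate_ml_s[flat_idx], rep(0, length(flat_idx)))
})

test_that("integrating the filling rate reproduces a noiseless curve", {
  p <- curve_params(n_frames = 94) # ~10 ms sampling
  sim <- simulate_volume_curve(p)
  rate <- derive_filling_rate(sim$curve)
  back <- integrate_filling_rate(rate, v0 = sim$curve$volume_ml[1])
  expect_lt(max(abs(back$volume_ml - sim$curve$volume_ml)), 0.5)
  # cyclic integral of dV/dt vanishes on the uniform grid (conservation)
  tc <- c(rate$time_ms, p$rr)
  rc <- c(rate$rate_ml_s, rate$rate_ml_s[1]) / 1000
  resid <- sum((rc[-1] + rc[-length(rc)]) / 2 * diff(tc))
  expect_lt(abs(resid), 1e-9)
})

test_that("dense spectral rate matches the analytic derivative", {
  p <- curve_params()
  sim <- simulate_volume_curve(p)
  dense <- dense_filling_rate(sim$curve)
  ej_w <- (p$es_time - p$iso_delay) / 2
  true_rate <- 1000 * (
    -oracle_lobe(dense$time_ms, p$sv / ej_w, (p$es_time + p$iso_delay) / 2, ej_w) +
      oracle_lobe(dense$time_ms, p$e_amp / 1000, p$es_time + p$e_center, p$e_width) +
      oracle_lobe(dense$time_ms, p$a_amp / 1000, p$es_time + p$a_center, p$a_width)
  )
  expect_lt(max(abs(dense$rate_ml_s - true_rate)), 0.02 * p$e_amp)
})

test_that("mask stacks reduce to volumes by slice summation", {
  sq <- function(npx) {
    m <- matrix(0L, 20, 20)
    m[seq_len(npx)] <- 1L
    m
  }
  counts <- c(100, 60, 40, 30, 40, 60, 80, 95)
  frames <- lapply(counts, function(k) list(sq(k)))
  st <- mask_stack(frames, pixel_area_mm2 = 1, slice_thickness_mm = 8,
                   slice_gap_mm = 2, rr_interval = 800)
  vc <- volume_from_mask_stack(st)
  # 100 px x 1 mm^2 x 10 mm = 1000 mm^3 = 1.0 mL
  expect_equal(vc$volume_ml, counts * 10 / 1000)

  zero_frames <- lapply(counts, function(k) list(matrix(0L, 4, 4)))
  st0 <- mask_stack(zero_frames, 1, 8, 2, rr_interval = 800)
  expect_error(volume_from_mask_stack(st0), class = "lvd_error_structure")

  expect_error(mask_stack(list(), 1, 8, 2, 800), class = "lvd_error_structure")
  uneven <- list(list(sq(10)), list(sq(10), sq(10)))
  expect_error(mask_stack(uneven, 1, 8, 2, 800), class = "lvd_error_structure")
})

test_that("digitised ellipsoid volume approaches the analytic value", {
  a <- 40; b <- 25 # semi-axes: 40 mm along the slice axis, 25 mm in-plane
  digitise <- function(px) {
    centers <- seq(-35, 35, by = 10) # slice centres, 10 mm spacing
    lapply(centers, function(z) {
      r <- b * sqrt(max(1 - (z / a)^2, 0))
      g <- seq(-b + px / 2, b - px / 2, by = px)
      xy <- expand.grid(x = g, y = g)
      matrix(as.integer(xy$x^2 + xy$y^2 <= r^2), nrow = length(g))
    })
  }
  v_true <- 4 / 3 * pi * a * b * b / 1000 # mL
  vol_at <- function(px) {
    slices <- digitise(px)
    sum(vapply(slices, sum, numeric(1))) * px^2 * 10 / 1000
  }
  expect_lt(abs(vol_at(1) - v_true) / v_true, 0.05)
  # in-plane digitisation error (relative to the slice-summed analytic
  # volume, which removes the fixed slice-discretisation term) shrinks
  # roughly linearly with pixel size
  centers <- seq(-35, 35, by = 10)
  v_slices <- sum(pi * (b^2 * pmax(1 - (centers / a)^2, 0))) * 10 / 1000
  err1 <- abs(vol_at(1) - v_slices)
  err2 <- abs(vol_at(2) - v_slices)
  expect_lt(err1, err2)
  expect_lt(err1, 0.02 * v_slices)

  # the same slices flow through the mask-stack pathway unchanged
  slices <- digitise(1)
  frames <- c(lapply(1:7, function(i) slices), list(lapply(slices, function(m) {
    m[1:20, ] <- 0L # one eroded frame so that EDV > ESV holds
    m
  })))
  vc <- volume_from_mask_stack(mask_stack(frames, 1, 8, 2, rr_interval = 800))
  expect_equal(vc$volume_ml[1], vol_at(1))
})
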