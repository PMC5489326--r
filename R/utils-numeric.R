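# Shared numerical machinery: raised-cosine lobes, cyclic differentiation,
# sub-sample refinement. All internal times are milliseconds; rates are
# converted to per-second units (x 1000) only at user-facing boundaries.

# Raised-cosine lobe: peak `amp` at `center`, compact support
# [center - width, center + width], area = amp * width.
raised_cosine <- function(t, amp, center, width) {
  u <- t - center
  inside <- abs(u) <= width
  out <- numeric(length(t))
  out[inside] <- amp * 0.5 * (1 + cos(pi * u[inside] / width))
  out
}

# Running integral of the lobe from -Inf to t (closed form).
raised_cosine_cum <- function(t, amp, center, width) {
  u <- pmin(pmax(t - center, -width), width)
  amp * 0.5 * ((u + width) + (width / pi) * sin(pi * u / width))
}

# Central differences on a periodic grid. `period` closes the cycle:
# the left neighbour of the first sample is the last sample shifted by
# -period, and symmetrically at the right edge. Returns units of
# value-per-millisecond.
central_diff_cyclic <- function(times, values, period) {
  n <- length(times)
  stopifnot(n >= 3, length(values) == n)
  tl <- c(times[n] - period, times[-n])
  tr <- c(times[-1], times[1] + period)
  vl <- c(values[n], values[-n])
  vr <- c(values[-1], values[1])
  (vr - vl) / (tr - tl)
}

# Trigonometric interpolation machinery for periodic, uniformly sampled
# signals: the interpolant (or its derivative, Nyquist term dropped) is
# evaluated on a dense uniform grid by zero-padded inverse FFT. Non-uniform
# grids fall back to a periodic cubic spline.
trig_dense_eval <- function(times, values, period, n_dense, deriv = 0,
                            damp = FALSE) {
  n <- length(values)
  t_dense <- period * (0:(n_dense - 1)) / n_dense
  steps <- diff(c(times, period + times[1]))
  uniform <- max(abs(steps - steps[1])) < 1e-6 * steps[1] && abs(times[1]) < 1e-9
  if (!uniform) {
    f <- stats::splinefun(c(times, period + times[1]), c(values, values[1]),
                          method = "periodic")
    return(list(t = t_dense, y = f(t_dense, deriv = deriv)))
  }
  vh <- stats::fft(values)
  if (isTRUE(damp)) {
    # spectral-subtraction damping: the highest harmonics set the noise
    # floor; coefficients are shrunk by the estimated noise energy. Exact
    # signals lose almost nothing, white noise is strongly attenuated.
    amp2 <- Mod(vh)^2
    floor2 <- stats::median(amp2[top_harmonics(n)])
    shrink <- pmax(0, 1 - floor2 / amp2)
    shrink[1] <- 1
    vh <- vh * shrink
  }
  if (deriv == 1) {
    k <- c(0:floor(n / 2), -((ceiling(n / 2) - 1):1))
    if (n %% 2 == 0) k[n / 2 + 1] <- 0
    vh <- vh * (2i * pi * k / period)
  }
  half <- floor(n / 2)
  pad <- complex(n_dense)
  pad[1:(half + 1)] <- vh[1:(half + 1)]
  pad[(n_dense - (n - half - 2)):n_dense] <- vh[(half + 2):n]
  list(t = t_dense, y = Re(stats::fft(pad, inverse = TRUE)) / n)
}

trig_deriv_dense <- function(times, values, period, n_dense, damp = FALSE) {
  out <- trig_dense_eval(times, values, period, n_dense, deriv = 1, damp = damp)
  list(t = out$t, d = out$y)
}

# Indices of the highest-frequency Fourier coefficients (both signs).
top_harmonics <- function(n) {
  k <- c(0:floor(n / 2), -((ceiling(n / 2) - 1):1))
  which(abs(k) >= floor(n / 2) - 2 & k != 0)
}

# White-noise level of a periodic, uniformly sampled signal, estimated from
# the power of its highest harmonics (E|vh_k|^2 = n * sigma^2 for white
# noise). Smooth signal leaking into those harmonics makes this an upper
# bound, which is the conservative direction for deciding robustness.
signal_noise_sigma <- function(values) {
  n <- length(values)
  vh <- stats::fft(values)
  sqrt(stats::median(Mod(vh[top_harmonics(n)])^2) / n)
}

# 3-point moving average with cyclic wrap (optional rate smoothing).
moving_average3_cyclic <- function(x) {
  n <- length(x)
  (c(x[n], x[-n]) + x + c(x[-1], x[1])) / 3
}

# Vertex of the parabola through (t1,y1),(t2,y2),(t3,y3); used to refine
# a sampled extremum. Falls back to the middle sample when the three
# points are collinear or the vertex escapes the bracket.
parabolic_refine <- function(t3, y3) {
  d1 <- (y3[2] - y3[1]) / (t3[2] - t3[1])
  d2 <- (y3[3] - y3[2]) / (t3[3] - t3[2])
  curv <- (d2 - d1) / ((t3[3] - t3[1]) / 2)
  if (!is.finite(curv) || abs(curv) < 1e-12) {
    return(list(t = t3[2], y = y3[2]))
  }
  # vertex of the Newton-form quadratic through the three points
  tv <- (t3[1] + t3[2]) / 2 - d1 / curv
  if (tv < t3[1] || tv > t3[3]) {
    return(list(t = t3[2], y = y3[2]))
  }
  yv <- y3[1] + d1 * (tv - t3[1]) + (curv / 2) * (tv - t3[1]) * (tv - t3[2])
  list(t = tv, y = yv)
}

# Indices of strict local maxima; a plateau counts once, at its first
# sample. Endpoints are not maxima.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  idx <- integer(0)
  i <- 2
  while (i <= n - 1) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[i]) j <- j + 1
      if (j <= n - 1 && x[j + 1] < x[i]) idx <- c(idx, i)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  idx
}

# Indices of strict local minima (plateau: first sample), mirroring
# local_maxima().
local_minima <- function(x) local_maxima(-x)

# Cumulative trapezoidal integral, anchored at 0 for the first sample.
cumtrapz <- function(t, y) {
  n <- length(t)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(t)))
}

# p-value display convention used in cohort reports: two decimals above
# 0.01, four decimals down to 0.0001, "<0.0001" below.
format_p <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 1e-4) "<0.0001"
    else if (pi < 0.01) sprintf("%.4f", pi)
    else sprintf("%.2f", pi)
  }, character(1))
}
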