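# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, dense-grid evaluation,
# and closed-form arithmetic.

# Dense-grid evaluation of the continuous raised-cosine model behind
# simulate_volume_curve(), written from the lobe definition directly.
oracle_lobe <- function(t, amp, center, width) {
  ifelse(abs(t - center) <= width,
         amp * 0.5 * (1 + cos(pi * (t - center) / width)), 0)
}

# Brute-force two-sided Freeman-Halton p: enumerate every table with the
# observed margins (2 x C only; sufficient for the small test tables) and
# sum the probabilities of those no more probable than the observed table.
oracle_fisher_2xc <- function(tb) {
  stopifnot(nrow(tb) == 2)
  cs <- colSums(tb); rs <- rowSums(tb)
  logp <- function(x1) {
    x2 <- cs - x1
    sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(sum(cs)) -
      sum(lfactorial(x1)) - sum(lfactorial(x2))
  }
  grids <- lapply(cs, function(cj) 0:min(rs[1], cj))
  all_rows <- expand.grid(grids)
  all_rows <- all_rows[rowSums(all_rows) == rs[1], , drop = FALSE]
  lp <- apply(all_rows, 1, logp)
  sum(exp(lp)[lp <= logp(tb[1, ]) + 1e-7])
}

# All-pairs AUC: fraction of (positive, negative) pairs ranked in the
# disease direction, ties counting one half.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# ICC(2,1) by explicit variance-components arithmetic on the two-way layout.
oracle_icc21 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_rows <- k * sum((rowMeans(m) - grand)^2)
  ss_cols <- n * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Dense-grid (1 ms) re-run of the deceleration-time procedure: least-squares
# line over the descending limb of the rate curve, extrapolated to zero.
oracle_dense_dt <- function(rate_fun, peak_time, search_end) {
  t <- seq(peak_time, search_end, by = 1)
  r <- rate_fun(t)
  j <- 1
  while (j < length(r) && r[j + 1] < r[j]) j <- j + 1
  win <- 1:j
  fit <- lm(r[win] ~ t[win])
  unname(-coef(fit)[1] / coef(fit)[2]) - peak_time
}

# Random valid curve parameters for recovery properties. Lobes are placed
# with explicit margins so that every draw is a physiologically plausible,
# well-posed two-lobe cycle.
random_curve_params <- function() {
  rr <- runif(1, 900, 1100)
  es <- runif(1, 0.32, 0.37) * rr
  avail <- rr - es
  e_w <- runif(1, 150, 185)
  a_w <- runif(1, 75, min(95, (avail - 2 * e_w - 45) / 2))
  e_amp <- runif(1, 150, 260)
  e_frac <- runif(1, 0.55, 0.72)
  a_amp <- (e_amp * e_w) * (1 / e_frac - 1) / a_w
  e_center <- e_w + runif(1, 8, 22)
  a_center <- avail - a_w - runif(1, 8, 20)
  sv <- (e_amp * e_w + a_amp * a_w) / 1000
  curve_params(rr = rr, n_frames = 30, edv = sv + runif(1, 30, 60), sv = NULL,
               es_time = es, e_center = e_center, e_width = e_w,
               a_center = a_center, a_width = a_w,
               e_amp = e_amp, a_amp = a_amp, noise_sd = 0)
}
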