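# Method-agreement statistics for echo-vs-CMR validation: one-way ANOVA
# (raw or summary form), exact r x c contingency tests, Pearson regression,
# Bland-Altman, rank-based ROC AUC with fit bands, ICC(2,1) with agreement
# bands, and the paired modality comparison.

#' One-way ANOVA from raw per-group values
#'
#' Classic equal-variance omnibus F test on (k-1, N-k) degrees of freedom.
#'
#' @param data Data frame.
#' @param value,group Column names (tidy-eval) of the measure and the
#'   grouping variable.
#' @return One-row tibble: `statistic` (F), `df`, `df_residual`, `p.value`.
#' @export
anova_oneway <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  ok <- complete.cases(v, g)
  v <- v[ok]; g <- droplevels(g[ok])
  ns <- table(g)
  if (nlevels(g) < 2 || any(ns < 2)) {
    abort("Need at least 2 groups with n >= 2 each.", class = "lvd_error_argument")
  }
  sums <- tapply(v, g, function(x) c(n = length(x), mean = mean(x), sd = sd(x)))
  sm <- do.call(rbind, sums)
  anova_oneway_summary(tibble::tibble(n = sm[, "n"], mean = sm[, "mean"],
                                      sd = sm[, "sd"]))
}

#' One-way ANOVA from group summary statistics
#'
#' Recovers the omnibus F exactly from per-group n/mean/SD: the
#' between-group sum of squares comes from the group means about the grand
#' mean and the within-group sum of squares is `sum((n_i - 1) * sd_i^2)`.
#' On data whose per-group moments match, this equals the raw-data ANOVA
#' exactly.
#'
#' @param summary Data frame with columns `n`, `mean`, `sd` (one row per
#'   group).
#' @return One-row tibble: `statistic`, `df`, `df_residual`, `p.value`.
#' @examples
#' anova_oneway_summary(data.frame(
#'   n = c(66, 21, 15),
#'   mean = c(220.14, 247.95, 258.4),
#'   sd = c(45.19, 76.70, 77.69)
#' ))
#' @export
anova_oneway_summary <- function(summary) {
  summary <- tibble::as_tibble(summary)
  if (!all(c("n", "mean", "sd") %in% names(summary))) {
    abort("`summary` needs columns n, mean, sd.", class = "lvd_error_schema")
  }
  n <- summary$n; m <- summary$mean; s <- summary$sd
  if (length(n) < 2 || any(n < 2) || any(s < 0)) {
    abort("Need >= 2 groups, each n >= 2, with non-negative SDs.",
          class = "lvd_error_argument")
  }
  k <- length(n); N <- sum(n)
  grand <- sum(n * m) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * s^2)
  if (ssw == 0 && ssb == 0) {
    abort("Zero within-group variance with equal means: F is undefined.",
          class = "lvd_error_degenerate")
  }
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  tibble::tibble(statistic = f, df = k - 1, df_residual = N - k,
                 p.value = pf(f, k - 1, N - k, lower.tail = FALSE))
}

#' Bonferroni-adjusted pairwise contrasts
#'
#' Post hoc pairwise t tests with Bonferroni correction, using the pooled
#' within-group variance. Secondary output alongside the omnibus ANOVA.
#'
#' @inheritParams anova_oneway
#' @return Tibble with one row per group pair: `group1`, `group2`,
#'   `estimate`, `p.value` (adjusted).
#' @export
bonferroni_pairwise <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  ok <- complete.cases(v, g)
  pt_res <- stats::pairwise.t.test(v[ok], droplevels(g[ok]),
                                   p.adjust.method = "bonferroni")
  means <- tapply(v[ok], droplevels(g[ok]), mean)
  pm <- pt_res$p.value
  out <- expand.grid(group1 = rownames(pm), group2 = colnames(pm),
                     stringsAsFactors = FALSE)
  out$p.value <- as.vector(pm)
  out <- out[!is.na(out$p.value), , drop = FALSE]
  out$estimate <- means[out$group1] - means[out$group2]
  tibble::as_tibble(out[, c("group1", "group2", "estimate", "p.value")])
}

#' Exact test of independence for an r x c contingency table
#'
#' Two-sided exact p-value in the Freeman-Halton sense: the probabilities of
#' all tables with the observed margins whose hypergeometric probability
#' does not exceed that of the observed table are summed. Enumeration is
#' used up to `enum_limit` total counts; beyond that a seeded Monte-Carlo
#' estimate is returned.
#'
#' @param table Matrix (or table) of non-negative integer counts.
#' @param enum_limit Largest table total enumerated exactly.
#' @param mc_draws Monte-Carlo replicates for the fallback.
#' @param seed Seed for the fallback.
#' @return One-row tibble: `p.value`, `method`.
#' @examples
#' fisher_exact_rxc(rbind(c(41, 11, 6), c(25, 10, 9)))
#' @export
fisher_exact_rxc <- function(table, enum_limit = 200, mc_draws = 1e5,
                             seed = NULL) {
  tb <- as.matrix(table)
  if (any(tb < 0) || any(tb != round(tb)) || sum(tb) == 0) {
    abort("`table` must be non-negative integer counts with a positive total.",
          class = "lvd_error_argument")
  }
  if (sum(tb) <= enum_limit) {
    p <- fisher.test(tb, workspace = 2e7)$p.value
    method <- "exact enumeration"
  } else {
    if (!is.null(seed)) set.seed(seed)
    p <- fisher.test(tb, simulate.p.value = TRUE, B = mc_draws)$p.value
    method <- sprintf("Monte Carlo (%d draws)", as.integer(mc_draws))
  }
  tibble::tibble(p.value = min(p, 1), method = method)
}

#' Pearson correlation and least-squares regression
#'
#' Linear association between a predictor (here, the echocardiographic
#' measure) and a response (the CMR measure): Pearson's r with its
#' two-sided t-transform p-value, plus the least-squares slope and
#' intercept with `x` as predictor.
#'
#' @param data Data frame.
#' @param x,y Column names (tidy-eval): predictor and response.
#' @return One-row tibble: `estimate` (r), `p.value`, `slope`, `intercept`,
#'   `n`.
#' @export
pearson_linear <- function(data, x, y) {
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  ok <- complete.cases(xv, yv) & is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) {
    abort("Need at least 3 complete pairs.", class = "lvd_error_argument")
  }
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("Zero variance in x or y: the correlation is undefined.",
          class = "lvd_error_degenerate")
  }
  ct <- stats::cor.test(xv, yv, method = "pearson")
  fit <- lm(yv ~ xv)
  tibble::tibble(estimate = unname(ct$estimate), p.value = ct$p.value,
                 slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 n = length(xv))
}

#' Bland-Altman limits of agreement
#'
#' Bias is the mean paired difference `y - x`; the 95% limits of agreement
#' are bias +/- 1.96 SD of the differences. Both series must be in the same
#' units -- comparing measures in different units is a contract error, not a
#' statistical question.
#'
#' @param x,y Paired measurements, same units.
#' @param units Optional unit labels for `x` and `y`; if both are given and
#'   differ, an error is raised.
#' @return Object of class `bland_altman`; [tidy()] returns `bias`,
#'   `loa_low`, `loa_high`, `sd_diff`, `n`, and [autoplot()] draws the
#'   agreement plot.
#' @export
bland_altman <- function(x, y, units = NULL) {
  if (!is.null(units) && length(units) == 2 && units[1] != units[2]) {
    abort(sprintf("Bland-Altman requires identical units; got '%s' vs '%s'.",
                  units[1], units[2]),
          class = "lvd_error_units")
  }
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) {
    abort("Need at least 2 complete pairs.", class = "lvd_error_argument")
  }
  d <- y - x
  bias <- mean(d)
  s <- sd(d)
  structure(
    list(bias = bias, sd_diff = s,
         loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
         n = length(d),
         data = tibble::tibble(mean = (x + y) / 2, diff = d)),
    class = "bland_altman"
  )
}

#' @exportS3Method generics::tidy
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, loa_low = x$loa_low, loa_high = x$loa_high,
                 sd_diff = x$sd_diff, n = x$n)
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f, 95%% limits of agreement %.3f to %.3f\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "#2c3e50") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "#c0392b") +
    ggplot2::labs(x = "Mean of paired measures", y = "Difference (y - x)") +
    ggplot2::theme_minimal()
}

# AUC fit bands: >= 0.5 to < 0.7 poor, >= 0.7 to < 0.9 good, >= 0.9
# excellent. AUCs below chance are reported as "poor".
auc_band <- function(auc) {
  dplyr::case_when(auc >= 0.9 ~ "excellent", auc >= 0.7 ~ "good",
                   .default = "poor")
}

# ICC agreement bands: < 0.40 poor, 0.40 to 0.75 fair-to-good,
# > 0.75 excellent.
icc_band <- function(icc) {
  dplyr::case_when(icc > 0.75 ~ "excellent", icc >= 0.40 ~ "fair-to-good",
                   .default = "poor")
}

#' ROC AUC from the rank statistic, with a fit band
#'
#' The area under the ROC curve is computed as the tie-corrected
#' Mann-Whitney statistic `U / (n1 * n0)` (ties count one half), i.e. the
#' probability that a randomly chosen diseased subject scores more extreme
#' than a randomly chosen healthy one in the disease direction. The
#' two-sided p-value uses the normal approximation to the rank statistic
#' with the tie correction. Intended use: reduced diastolic function as the
#' positive class versus normal function as the negative class, with
#' intermediate (type I) subjects excluded before the call.
#'
#' @param scores Numeric marker values.
#' @param labels Logical (or coercible) disease indicator, `TRUE` =
#'   positive class.
#' @param direction `"higher"` if larger scores indicate disease (E/E', NE,
#'   DT), `"lower"` if smaller scores do (E').
#' @return Object of class `roc_result`; [tidy()] gives `auc`, `band`,
#'   `p.value`, `n_pos`, `n_neg`.
#' @export
roc_auc_with_band <- function(scores, labels, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  ok <- complete.cases(scores, labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    abort("Both classes must be present to compute an AUC.",
          class = "lvd_error_degenerate_labels")
  }
  s <- if (direction == "lower") -scores else scores
  rk <- rank(s)
  u <- sum(rk[labels]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  n <- n1 + n0
  ties <- table(s)
  sigma2 <- (n1 * n0 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  p <- if (sigma2 <= 0) 1 else 2 * pnorm(-abs(u - n1 * n0 / 2) / sqrt(sigma2))
  structure(
    list(auc = auc, band = auc_band(auc), p.value = min(p, 1),
         n_pos = n1, n_neg = n0, direction = direction,
         data = tibble::tibble(score = s, label = labels)),
    class = "roc_result"
  )
}

#' @exportS3Method generics::tidy
tidy.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, band = x$band, p.value = x$p.value,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC AUC %.3f (%s fit), p = %s [%d positive / %d negative]\n",
              x$auc, x$band, format_p(x$p.value), x$n_pos, x$n_neg))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.roc_result <- function(object, ...) {
  thr <- sort(unique(object$data$score), decreasing = TRUE)
  pts <- purrr::map_dfr(c(Inf, thr, -Inf), function(th) {
    tibble::tibble(
      fpr = mean(object$data$score[!object$data$label] >= th),
      tpr = mean(object$data$score[object$data$label] >= th)
    )
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(colour = "#2c3e50") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = sprintf("AUC = %.2f (%s)", object$auc, object$band)) +
    ggplot2::theme_minimal()
}

#' Two-way random, single-measure, absolute-agreement ICC
#'
#' ICC(2,1) from the two-way mean-squares decomposition with subjects and
#' raters both treated as random:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`. The agreement
#' band follows the conventional cutoffs (poor < 0.40, fair-to-good 0.40 to
#' 0.75, excellent > 0.75). For two raters the Bland-Altman bias and limits
#' are attached.
#'
#' @param ratings Numeric matrix or data frame, subjects in rows, raters in
#'   columns; complete, >= 5 subjects, >= 2 raters.
#' @return Object of class `agreement_result`; [tidy()] gives `icc`, `band`,
#'   `bias`, `loa_low`, `loa_high`, `n`, `k`.
#' @export
icc_two_way_random <- function(ratings) {
  m <- as.matrix(ratings)
  n <- nrow(m); k <- ncol(m)
  if (n < 5 || k < 2) {
    abort("Need >= 5 subjects and >= 2 raters.", class = "lvd_error_argument")
  }
  if (anyNA(m)) {
    abort("The ratings matrix must be complete.",
          class = "lvd_error_incomplete_matrix")
  }
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  ba <- if (k == 2) bland_altman(m[, 1], m[, 2]) else NULL
  structure(
    list(icc = icc, band = icc_band(icc),
         bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
         n = n, k = k,
         mean_squares = c(msr = msr, msc = msc, mse = mse)),
    class = "agreement_result"
  )
}

#' @exportS3Method generics::tidy
tidy.agreement_result <- function(x, ...) {
  tibble::tibble(icc = x$icc, band = x$band,
                 bias = x$bias %||% NA_real_,
                 loa_low = x$loa_low %||% NA_real_,
                 loa_high = x$loa_high %||% NA_real_,
                 n = x$n, k = x$k)
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f (%s agreement), %d subjects x %d raters\n",
              x$icc, x$band, x$n, x$k))
  if (!is.null(x$bias)) {
    cat(sprintf("  bias %.3f, 95%% limits of agreement %.3f to %.3f\n",
                x$bias, x$loa_low, x$loa_high))
  }
  invisible(x)
}

#' Paired comparison of two modalities
#'
#' Paired t test on same-subject measurements (e.g. CMR versus echo cycle
#' length); identical series return t = 0, p = 1 rather than failing on
#' zero variance.
#'
#' @param x,y Paired measurements, same units.
#' @return One-row tibble: `estimate` (mean of `y - x`), `statistic`, `df`,
#'   `p.value`, `n`.
#' @export
paired_mean_comparison <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) {
    abort("Need at least 2 complete pairs.", class = "lvd_error_argument")
  }
  d <- y - x
  if (sd(d) == 0) {
    return(tibble::tibble(estimate = mean(d),
                          statistic = if (mean(d) == 0) 0 else Inf,
                          df = length(d) - 1,
                          p.value = if (mean(d) == 0) 1 else 0,
                          n = length(d)))
  }
  tt <- t.test(y, x, paired = TRUE)
  tibble::tibble(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p.value = tt$p.value, n = length(d))
}
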